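test_that("identity GRM reduces REML to the closed-form OLS likelihood", {
  set.seed(1)
  n <- 60
  ids <- sprintf("a%02d", 1:n)
  y <- rnorm(n, 2)
  d <- data.frame(animal_id = ids, trait = "t", y = y)
  GI <- new_grm(diag(n), ids, 1)
  vc <- fit_greml(d, GI)
  ## total variance is identified, the split is not
  expect_false(vc$identifiable)
  X <- matrix(1, n, 1)
  rss <- sum(lm.fit(X, y)$residuals^2)
  s2 <- rss / (n - 1)
  logl_ols <- -0.5 * ((n - 1) * log(s2) + log(n) + rss / s2)
  expect_equal(vc$log_likelihood, as.numeric(logl_ols), tolerance = 1e-6)
  expect_equal(vc$P[1, 1] + vc$R[1, 1], s2, tolerance = 1e-4)
})

test_that("REML optimum matches an exhaustive likelihood grid (small n)", {
  set.seed(2)
  b <- simulate_bundle(sim_config(n_countries = 1, animals_per_country = 40,
                                  n_sequence_variants = 400, n_qtl = 50,
                                  h2 = 0.4, rg = matrix(1),
                                  qtl_on_array = TRUE, seed = 5))
  G <- build_grm_yang(b$genotypes, maf_min = 0.05)
  d <- trait_records(b$animals)
  vc <- fit_greml(d, G)
  eig <- eigen(G$matrix, symmetric = TRUE)
  lam <- pmax(eig$values, 1e-8)
  yt <- crossprod(eig$vectors, d$y)
  xt <- crossprod(eig$vectors, rep(1, 40))
  grid <- seq(0.005, 1.5, by = 0.005)
  best <- c(NA, NA); bestL <- -Inf
  for (sg in grid) {
    dm <- outer(sg * lam, rep(1, length(grid))) + rep(grid, each = 40)
    Di <- 1 / dm
    xvx <- colSums(xt[, 1]^2 * Di)
    yvy <- colSums(yt[, 1]^2 * Di)
    xvy <- colSums(yt[, 1] * xt[, 1] * Di)
    L <- -0.5 * (colSums(log(dm)) + log(xvx) + yvy - xvy^2 / xvx)
    j <- which.max(L)
    if (L[j] > bestL) { bestL <- L[j]; best <- c(sg, grid[j]) }
  }
  expect_lt(abs(vc$P[1, 1] - best[1]), 0.005)
  expect_lt(abs(vc$R[1, 1] - best[2]), 0.005)
  expect_gte(vc$log_likelihood, bestL - 1e-6)
})

test_that("heritability and genetic correlation are delta-method summaries", {
  vc <- structure(list(P = matrix(0.30), R = matrix(0.70),
                       traits = "t",
                       desc = list(list(kind = "P", t1 = 1, t2 = 1),
                                   list(kind = "R", t1 = 1, t2 = 1)),
                       vcov_theta = diag(c(1e-4, 1e-4)),
                       converged = TRUE), class = "varcomp")
  h <- heritability(vc)
  expect_equal(unname(h["h2"]), 0.30)
  vc$P <- matrix(0); expect_equal(unname(heritability(vc)["h2"]), 0)
  P <- matrix(c(1, 0.95, 0.95, 1), 2)
  vc2 <- structure(list(P = P, R = diag(2), traits = c("a", "b"),
                        desc = list(list(kind = "P", t1 = 1, t2 = 1),
                                    list(kind = "P", t1 = 1, t2 = 2),
                                    list(kind = "P", t1 = 2, t2 = 2),
                                    list(kind = "R", t1 = 1, t2 = 1),
                                    list(kind = "R", t1 = 2, t2 = 2)),
                        vcov_theta = diag(5) * 1e-4,
                        converged = TRUE), class = "varcomp")
  expect_equal(unname(genetic_correlation(vc2)["rg"]), 0.95)
  vc2$P[1, 2] <- vc2$P[2, 1] <- 0
  expect_equal(unname(genetic_correlation(vc2)["rg"]), 0)
  vc2$P[1, 1] <- 0
  rg0 <- genetic_correlation(vc2)
  expect_true(is.nan(rg0["rg"]))
  expect_match(attr(rg0, "reason"), "zero genetic variance")
})

test_that("GBLUP equals the SNP ridge-regression dual", {
  b <- simulate_bundle(sim_config(n_countries = 1, animals_per_country = 200,
                                  n_sequence_variants = 500, n_qtl = 100,
                                  h2 = 0.4, rg = matrix(1),
                                  qtl_on_array = TRUE, seed = 9))
  g <- b$genotypes
  X <- impute_mean(g$dosages); p <- colMeans(X) / 2
  keep <- pmin(p, 1 - p) >= 0.01
  Z <- sweep(X[, keep], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  mk <- ncol(Z)
  G <- new_grm(tcrossprod(Z) / mk, g$animal_ids, mk)
  d <- trait_records(b$animals)
  vc <- fit_greml(d, G)
  pr <- predict_gebv(d, G, vc)
  r <- d$y - as.numeric(pr$fixed)
  alpha <- solve(crossprod(Z) + diag(mk * vc$R[1, 1] / vc$P[1, 1], mk),
                 crossprod(Z, r))
  expect_gt(cor(Z %*% alpha, pr$gebv[, 1]), 0.9999)
})

test_that("prediction limits and invariances hold", {
  set.seed(4)
  n <- 50; ids <- sprintf("i%02d", 1:n); y <- rnorm(n)
  GI <- new_grm(diag(n), ids, 10)
  d <- data.frame(animal_id = ids, trait = "t", y = y)
  ## h2 -> 1 shrinkage limit: GEBV -> centered phenotypes
  vc1 <- list(P = matrix(1), R = matrix(1e-8), traits = "t", converged = TRUE)
  pr1 <- predict_gebv(d, GI, vc1)
  expect_lt(max(abs(pr1$gebv[, 1] - (y - mean(y)))), 1e-6)
  ## invariance to shifting the response (estimable-function invariance)
  d2 <- d; d2$y <- d$y + 5
  pr2 <- predict_gebv(d2, GI, vc1)
  expect_lt(max(abs(pr2$gebv[, 1] - pr1$gebv[, 1])), 1e-8)
  ## unconverged fits are refused without force
  vcx <- vc1; vcx$converged <- FALSE
  expect_error(predict_gebv(d, GI, vcx), "converge")
})

test_that("masked-animal GEBV equal the conditional-expectation oracle", {
  b <- small_bundle(seed = 5)
  G <- build_grm_yang(b$genotypes, maf_min = "auto")
  d <- trait_records(b$animals)
  set.seed(1)
  vids <- sample(d$animal_id, 40)
  tr <- d[!d$animal_id %in% vids, ]
  vc <- fit_greml(tr, G)
  pr <- predict_gebv(d, G, vc, mask = vids, force = TRUE)
  ti <- match(tr$animal_id, G$animal_ids)
  vi <- match(vids, G$animal_ids)
  V <- vc$P[1, 1] * G$matrix[ti, ti] + diag(vc$R[1, 1], length(ti))
  Xt <- model.matrix(~ factor(tr$dataset))
  bh <- solve(crossprod(Xt, solve(V, Xt)), crossprod(Xt, solve(V, tr$y)))
  oracle <- vc$P[1, 1] * G$matrix[vi, ti] %*% solve(V, tr$y - Xt %*% bh)
  expect_lt(max(abs(oracle - pr$gebv[vids, 1])), 1e-8)
})

test_that("a unit genetic correlation makes bivariate and pooled GBLUP agree", {
  cfg <- sim_config(n_countries = 2, animals_per_country = c(150, 150),
                    n_sires_per_country = 15, n_sequence_variants = 800,
                    n_qtl = 60, qtl_on_array = TRUE,
                    h2 = 0.3, rg = matrix(1), country_fst = 0, seed = 6)
  b <- simulate_bundle(cfg)
  G <- build_grm_yang(b$genotypes, maf_min = "auto")
  an <- b$animals
  duni <- trait_records(an)
  dbiv <- rbind(trait_records(an, trait = "c1", datasets = "P1"),
                trait_records(an, trait = "c2", datasets = "P2"))
  vcu <- fit_greml(duni, G)
  vg <- vcu$P[1, 1]; ve <- vcu$R[1, 1]
  ## model-equivalence oracle: bivariate components set to the rg = 1,
  ## equal-variance values implied by the pooled univariate fit
  vcb <- list(P = matrix(vg, 2, 2), R = diag(ve, 2),
              traits = c("c1", "c2"), converged = TRUE)
  pru <- predict_gebv(duni, G, vcu, force = TRUE)
  prb <- predict_gebv(dbiv, G, vcb, force = TRUE)
  ids1 <- an$animal_id[an$dataset == "P1"]
  expect_gt(cor(prb$gebv[ids1, "c1"], pru$gebv[ids1, 1]), 0.99)
})

test_that("disjoint cohorts fix the residual covariance at zero", {
  b <- small_bundle(seed = 7)
  G <- build_grm_yang(b$genotypes, maf_min = "auto")
  dbiv <- rbind(trait_records(b$animals, trait = "c1", datasets = "P1"),
                trait_records(b$animals, "y_trait2", trait = "c2",
                              datasets = "P2"))
  vc <- fit_greml(dbiv, G)
  expect_equal(vc$R[1, 2], 0)
  expect_true(is.na(vc$se_R[1, 2]))
})
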