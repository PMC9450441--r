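test_that("the generator is fully deterministic given the seed", {
  b1 <- small_bundle(seed = 11)
  b2 <- small_bundle(seed = 11)
  expect_identical(b1$genotypes$dosages, b2$genotypes$dosages)
  expect_identical(b1$animals, b2$animals)
  expect_identical(b1$records, b2$records)
  b3 <- small_bundle(seed = 12)
  expect_false(identical(b1$genotypes$dosages, b3$genotypes$dosages))
})

test_that("no drift means no differentiation", {
  cfg <- sim_config(n_countries = 3, animals_per_country = 150,
                    n_sires_per_country = 50, n_sequence_variants = 3000,
                    n_qtl = 20, country_fst = 0, seed = 2)
  sim <- simulate_genotypes(cfg)
  f <- pairwise_fst(sim$genotypes, sim$pedigree$dataset)
  expect_lt(max(f$gst[upper.tri(f$gst)]), 0.005)
})

test_that("realized FST tracks the drift parameter (frequency-only oracle)", {
  drift <- 0.02
  cfg <- sim_config(n_countries = 2, animals_per_country = 150,
                    n_sequence_variants = 3000, n_qtl = 20,
                    country_fst = c(drift, 0), n_founder_hap = 400, seed = 3)
  sim <- simulate_genotypes(cfg)
  f <- pairwise_fst(sim$genotypes, sim$pedigree$dataset)
  obs <- f$gst[1, 2]
  ## independent frequency-only simulator: haplotype alleles ~ Bern(p0),
  ## drifted country frequency = Dirichlet-weighted mean, then the same
  ## multi-locus G_ST estimator on the two frequency vectors
  oracle <- replicate(30, {
    m <- 3000; K <- 400
    p0 <- pmin(pmax(rbeta(m, 0.5, 0.5), 0.01), 0.99)
    H <- matrix(rbinom(K * m, 1, rep(p0, each = K)), K)
    a <- (1 / drift - 1) / K
    w <- rgamma(K, a); w <- w / sum(w)
    p1 <- colSums(H * w)
    p2 <- colMeans(H)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pb <- (p1 + p2) / 2
    ht <- 2 * pb * (1 - pb)
    sum(ht - hs) / sum(ht[ht > 0])
  })
  expect_lt(abs(obs - mean(oracle)), 3 * sd(oracle) + 3 * sd(oracle) / sqrt(30))
})

test_that("per-country heterozygosity sits in the Holstein-like band", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_genotypes(cfg)
  hd <- make_panel(sim$genotypes, "hd")
  het <- rowMeans(hd$dosages == 1)
  for (cc in unique(sim$pedigree$dataset)) {
    m <- mean(het[sim$pedigree$dataset == cc])
    expect_gte(m, 0.30); expect_lte(m, 0.36)
  }
})

test_that("panels obey their construction rules", {
  cfg <- sim_config(n_countries = 2, animals_per_country = 100,
                    n_sequence_variants = 2000, n_qtl = 50, seed = 4)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes
  expect_identical(make_panel(g, "sequence")$dosages, g$dosages)
  arr <- make_panel(g, "array50k")
  ## array keeps only common variants and never a causal one (default config)
  expect_true(all(arr$variants$maf >= 0.05))
  expect_false(any(arr$variants$is_qtl))
  common_nonqtl <- sum(g$variants$maf >= 0.05 & !g$variants$is_qtl)
  expect_equal(ncol(arr$dosages) / common_nonqtl, cfg$array_fraction,
               tolerance = 0.01)
  expect_error(make_panel(g, "nonesuch"), "unknown panel")
  ## ~60% of variants clear the imputation-quality threshold
  expect_gt(mean(g$variants$r2_ove > 0.4), 0.5)
  expect_lt(mean(g$variants$r2_ove > 0.4), 0.7)
})

test_that("trait generator hits its heritability and correlation targets", {
  ## h2 ~ 0: phenotype carries no genetic signal
  cfg0 <- sim_config(n_countries = 1, animals_per_country = 2000,
                     n_sires_per_country = 200, n_sequence_variants = 1000,
                     n_qtl = 100, h2 = 1e-4, rg = matrix(1), seed = 5)
  b0 <- simulate_bundle(cfg0)
  expect_lt(abs(cor(b0$animals$tbv_trait1, b0$animals$y_trait1)), 0.05)

  ## h2 = 0.30: regression of phenotype on true BV has slope ~ 1
  cfg3 <- sim_config(n_countries = 1, animals_per_country = 2000,
                     n_sires_per_country = 200, n_sequence_variants = 1000,
                     n_qtl = 100, h2 = 0.3, rg = matrix(1), seed = 6)
  b3 <- simulate_bundle(cfg3)
  sl <- coef(lm(b3$animals$y_trait1 ~ b3$animals$tbv_trait1))[2]
  se <- sqrt((1 - 0.3) / (0.3 * 2000))
  expect_lt(abs(sl - 1), 3 * se)

  ## configured rg is realized in the true breeding values
  cfgr <- sim_config(n_countries = 1, animals_per_country = 400,
                     n_sires_per_country = 40, n_sequence_variants = 4000,
                     n_qtl = 2000, qtl_maf_min = 0.01,
                     h2 = c(0.3, 0.3), rg = matrix(c(1, .95, .95, 1), 2),
                     seed = 7)
  br <- simulate_bundle(cfgr)
  expect_lt(abs(cor(br$animals$tbv_trait1, br$animals$tbv_trait2) - 0.95),
            0.03)
})

test_that("GRM of simulated data is Yang-normalized", {
  b <- small_bundle(seed = 9)
  G <- build_grm_yang(b$genotypes, maf_min = "auto")
  expect_gt(mean(diag(G$matrix)), 0.95)
  expect_lt(mean(diag(G$matrix)), 1.05)
})

test_that("derived cow RFI has a field-realistic spread", {
  b <- small_bundle(seed = 10)
  r <- derive_rfi(b$records, rfi_spec_cow())
  expect_gt(sd(r$rfi), 1.0)
  expect_lt(sd(r$rfi), 3.04)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_qtl = 100, n_sequence_variants = 50), "n_qtl")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(h2 = c(.3, .3), rg = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(sim_config(array_fraction = 0), "array_fraction")
})
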