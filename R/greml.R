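#' @name greml
#' @title GREML variance components and GBLUP breeding values
#'
#' @description
#' The multi-trait linear mixed model is `y_T = X_T b_T + Z_T g_T + e_T`
#' with `g ~ N(0, G (x) P)` and `e ~ N(0, R (x) I)`, where `G` is a genomic
#' relationship matrix, `P` the T x T additive-genetic and `R` the T x T
#' residual (co)variance matrix. Traits are typically the same biological
#' trait measured in different cohorts (countries), each animal carrying at
#' most one record per trait. Restricted maximum likelihood is maximised by
#' average-information (AI) updates with step-halving and an EM-flavoured
#' fallback whenever an AI step would leave the parameter space; standard
#' errors come from the inverse AI matrix at the optimum.
NULL

.vc_theta_pack <- function(Tn, overlap_ok) {
  desc <- list()
  for (a in seq_len(Tn)) for (b in a:Tn)
    desc[[length(desc) + 1L]] <- list(kind = "P", t1 = a, t2 = b)
  for (a in seq_len(Tn))
    desc[[length(desc) + 1L]] <- list(kind = "R", t1 = a, t2 = a)
  if (Tn > 1) for (a in seq_len(Tn - 1)) for (b in (a + 1):Tn)
    if (overlap_ok[a, b])
      desc[[length(desc) + 1L]] <- list(kind = "R", t1 = a, t2 = b)
  desc
}

.vc_unpack <- function(theta, desc, Tn) {
  P <- matrix(0, Tn, Tn); R <- matrix(0, Tn, Tn)
  for (j in seq_along(desc)) {
    d <- desc[[j]]
    if (d$kind == "P") P[d$t1, d$t2] <- P[d$t2, d$t1] <- theta[j]
    else R[d$t1, d$t2] <- R[d$t2, d$t1] <- theta[j]
  }
  list(P = P, R = R)
}

.bend_psd <- function(M, floor_frac = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  lo <- floor_frac * max(e$values, 1)
  if (min(e$values) >= lo) return(M)
  e$vectors %*% diag(pmax(e$values, lo), nrow(M)) %*% t(e$vectors)
}

.project_theta <- function(theta, desc, Tn) {
  m <- .vc_unpack(theta, desc, Tn)
  P <- .bend_psd(m$P); R <- .bend_psd(m$R)
  for (j in seq_along(desc)) {
    d <- desc[[j]]
    theta[j] <- if (d$kind == "P") P[d$t1, d$t2] else R[d$t1, d$t2]
  }
  theta
}

## ---- univariate fast path in the eigenbasis of G ----

.grm_eigen <- function(G) {
  e <- eigen(G, symmetric = TRUE)
  e$values <- pmax(e$values, 1e-8)   # bend to PSD
  e
}

.reml_uni <- function(y, X, eig, max_iter = 100, tol_logl = 1e-8,
                      tol_par = 1e-6) {
  U <- eig$vectors; lam <- eig$values
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  n <- length(yt); p <- ncol(Xt)
  vp <- stats::var(stats::residuals(stats::lm.fit(X, y)))
  theta <- c(vp / 2, vp / 2)
  eval_at <- function(th) {
    d <- th[1] * lam + th[2]
    Di <- 1 / d
    Mx <- Xt * Di
    XtVX <- crossprod(Xt, Mx)
    B <- solve(XtVX)
    MxB <- Mx %*% B
    Py <- Di * yt - MxB %*% crossprod(Mx, yt)
    logl <- -0.5 * (sum(log(d)) +
                      determinant(XtVX, logarithm = TRUE)$modulus +
                      sum(yt * Py))
    diagA <- rowSums(MxB * Mx)
    trP1 <- sum(lam * Di) - sum(lam * diagA)
    trP2 <- sum(Di) - sum(diagA)
    w1 <- lam * Py; w2 <- Py
    Pw <- function(w) Di * w - MxB %*% crossprod(Mx, w)
    Pw1 <- Pw(w1); Pw2 <- Pw(w2)
    q1 <- sum(Py * w1); q2 <- sum(Py * w2)
    grad <- -0.5 * c(trP1 - q1, trP2 - q2)
    AI <- 0.5 * matrix(c(sum(w1 * Pw1), sum(w1 * Pw2),
                         sum(w1 * Pw2), sum(w2 * Pw2)), 2)
    list(logl = as.numeric(logl), grad = grad, AI = AI,
         yPDPy = c(q1, q2), trP = c(trP1, trP2))
  }
  st <- eval_at(theta)
  converged <- FALSE; iter <- 0; identifiable <- TRUE; stall <- 0L
  for (iter in seq_len(max_iter)) {
    sv <- svd(st$AI)
    if (min(sv$d) < 1e-10 * max(sv$d)) {
      identifiable <- FALSE
      dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
    } else dinv <- 1 / sv$d
    step <- sv$v %*% (dinv * crossprod(sv$u, st$grad))
    ok <- FALSE
    for (h in 0:8) {                      # step halving
      cand <- pmax(theta + step / 2^h, 1e-8)
      st2 <- tryCatch(eval_at(cand), error = function(e) NULL)
      if (!is.null(st2) && st2$logl >= st$logl - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) {                            # EM-flavoured fallback
      cand <- pmax(theta + theta^2 / n * (st$yPDPy - st$trP), 1e-8)
      st2 <- tryCatch(eval_at(cand), error = function(e) NULL)
      if (is.null(st2) || st2$logl < st$logl - 1e-8) { converged <- TRUE; break }
    }
    dl <- st2$logl - st$logl
    dp <- max(abs(cand - theta) / pmax(abs(theta), 1e-6))
    theta <- cand; st <- st2
    if (abs(dl) < tol_logl && dp < tol_par) { converged <- TRUE; break }
    ## stalled at a constraint boundary: logL flat while a bent parameter
    ## keeps being projected back -- treat as converged at the boundary
    stall <- if (abs(dl) < 1e-4) stall + 1L else 0L
    if (stall >= 3L) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(diag(solve(st$AI))), error = function(e) rep(NA_real_, 2))
  vcov_th <- tryCatch(solve(st$AI), error = function(e) matrix(NA_real_, 2, 2))
  list(theta = theta, logl = st$logl, se = se, vcov = vcov_th,
       converged = converged, identifiable = identifiable, n_iter = iter)
}

## ---- general dense multivariate AI-REML ----

.reml_multi <- function(ylist, Xlist, aidx, G, overlap_min = 30,
                        max_iter = 60, tol_logl = 1e-8, tol_par = 1e-6) {
  Tn <- length(ylist)
  nrec <- vapply(ylist, length, 0L)
  offs <- cumsum(c(0L, nrec))
  N <- sum(nrec)
  blk <- lapply(seq_len(Tn), function(t) (offs[t] + 1L):offs[t + 1L])
  K <- vector("list", Tn)
  for (a in seq_len(Tn)) {
    K[[a]] <- vector("list", Tn)
    for (b in a:Tn) K[[a]][[b]] <- G[aidx[[a]], aidx[[b]], drop = FALSE]
  }
  ## residual-covariance identifiability: need enough animals with both traits
  overlap_ok <- matrix(FALSE, Tn, Tn)
  shared <- list()
  if (Tn > 1) for (a in seq_len(Tn - 1)) for (b in (a + 1):Tn) {
    common <- intersect(aidx[[a]], aidx[[b]])
    if (length(common) >= overlap_min) {
      overlap_ok[a, b] <- TRUE
      shared[[paste(a, b)]] <- cbind(
        blk[[a]][match(common, aidx[[a]])],
        blk[[b]][match(common, aidx[[b]])])
    }
  }
  desc <- .vc_theta_pack(Tn, overlap_ok)
  q <- length(desc)
  y <- unlist(ylist)
  X <- matrix(0, N, sum(vapply(Xlist, ncol, 0L)))
  cs <- cumsum(c(0L, vapply(Xlist, ncol, 0L)))
  for (t in seq_len(Tn))
    X[blk[[t]], (cs[t] + 1L):cs[t + 1L]] <- Xlist[[t]]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("fixed-effect design is rank deficient; reduced to rank ",
            qrX$rank)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  ## starting values
  theta <- numeric(q)
  vps <- vapply(seq_len(Tn), function(t)
    stats::var(stats::residuals(stats::lm.fit(Xlist[[t]], ylist[[t]]))), 0)
  for (j in seq_len(q)) {
    d <- desc[[j]]
    theta[j] <- if (d$t1 == d$t2) vps[d$t1] / 2
      else if (d$kind == "P") 0.3 * sqrt(vps[d$t1] * vps[d$t2]) / 2
      else 0
  }
  build_V <- function(th) {
    V <- matrix(0, N, N)
    for (j in seq_len(q)) {
      d <- desc[[j]]
      if (d$kind == "P") {
        if (d$t1 == d$t2) {
          V[blk[[d$t1]], blk[[d$t1]]] <- V[blk[[d$t1]], blk[[d$t1]]] +
            th[j] * K[[d$t1]][[d$t1]]
        } else {
          V[blk[[d$t1]], blk[[d$t2]]] <- V[blk[[d$t1]], blk[[d$t2]]] +
            th[j] * K[[d$t1]][[d$t2]]
          V[blk[[d$t2]], blk[[d$t1]]] <- t(V[blk[[d$t1]], blk[[d$t2]]])
        }
      } else if (d$t1 == d$t2) {
        ii <- blk[[d$t1]]
        V[cbind(ii, ii)] <- V[cbind(ii, ii)] + th[j]
      } else {
        sh <- shared[[paste(d$t1, d$t2)]]
        V[sh] <- V[sh] + th[j]
        V[sh[, 2:1, drop = FALSE]] <- V[sh[, 2:1, drop = FALSE]] + th[j]
      }
    }
    V
  }
  eval_logl <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    u <- backsolve(ch, backsolve(ch, cbind(y, X), transpose = TRUE))
    Viy <- u[, 1]; ViX <- u[, -1, drop = FALSE]
    XtViX <- crossprod(X, ViX)
    B <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(B)) return(NULL)
    yPy <- sum(y * Viy) - drop(crossprod(crossprod(ViX, y), B %*% crossprod(X, Viy)))
    as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                         determinant(XtViX, logarithm = TRUE)$modulus + yPy))
  }
  eval_at <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    B <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(B)) return(NULL)
    Pm <- Vi - ViX %*% tcrossprod(B, ViX)
    Py <- Pm %*% y
    logl <- -0.5 * (2 * sum(log(diag(ch))) +
                      determinant(XtViX, logarithm = TRUE)$modulus +
                      sum(y * Py))
    W <- matrix(0, N, q)
    trPB <- numeric(q); yPBPy <- numeric(q)
    for (j in seq_len(q)) {
      d <- desc[[j]]
      if (d$kind == "P") {
        if (d$t1 == d$t2) {
          i1 <- blk[[d$t1]]
          trPB[j] <- sum(Pm[i1, i1] * K[[d$t1]][[d$t1]])
          W[i1, j] <- K[[d$t1]][[d$t1]] %*% Py[i1]
        } else {
          i1 <- blk[[d$t1]]; i2 <- blk[[d$t2]]
          trPB[j] <- 2 * sum(Pm[i1, i2] * K[[d$t1]][[d$t2]])
          W[i1, j] <- K[[d$t1]][[d$t2]] %*% Py[i2]
          W[i2, j] <- crossprod(K[[d$t1]][[d$t2]], Py[i1])
        }
      } else if (d$t1 == d$t2) {
        i1 <- blk[[d$t1]]
        trPB[j] <- sum(diag(Pm)[i1])
        W[i1, j] <- Py[i1]
      } else {
        sh <- shared[[paste(d$t1, d$t2)]]
        trPB[j] <- 2 * sum(Pm[sh])
        W[sh[, 1], j] <- W[sh[, 1], j] + Py[sh[, 2]]
        W[sh[, 2], j] <- W[sh[, 2], j] + Py[sh[, 1]]
      }
      yPBPy[j] <- sum(Py * W[, j])
    }
    AI <- 0.5 * crossprod(W, Pm %*% W)
    grad <- -0.5 * (trPB - yPBPy)
    list(logl = as.numeric(logl), grad = grad, AI = AI,
         trPB = trPB, yPBPy = yPBPy)
  }
  st <- eval_at(theta)
  if (is.null(st)) stop("variance matrix singular at starting values")
  converged <- FALSE; identifiable <- TRUE; iter <- 0; stall <- 0L
  for (iter in seq_len(max_iter)) {
    sv <- svd(st$AI)
    if (min(sv$d) < 1e-10 * max(sv$d)) identifiable <- FALSE
    dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
    step <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, st$grad)))
    ok <- FALSE
    for (h in 0:6) {                      # halving on the cheap evaluator
      cand <- .project_theta(theta + step / 2^h, desc, Tn)
      l2 <- eval_logl(cand)
      if (!is.null(l2) && l2 >= st$logl - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) {
      cand <- .project_theta(theta + theta^2 / N * (st$yPBPy - st$trPB),
                             desc, Tn)
      l2 <- eval_logl(cand)
      if (is.null(l2) || l2 < st$logl - 1e-8) { converged <- TRUE; break }
    }
    st2 <- eval_at(cand)
    if (is.null(st2)) { converged <- FALSE; break }
    dl <- st2$logl - st$logl
    dp <- max(abs(cand - theta) / pmax(abs(theta), 1e-6))
    theta <- cand; st <- st2
    if (abs(dl) < tol_logl && dp < tol_par) { converged <- TRUE; break }
    stall <- if (abs(dl) < 1e-4) stall + 1L else 0L
    if (stall >= 3L) { converged <- TRUE; break }
  }
  vcov_th <- tryCatch(solve(st$AI), error = function(e) matrix(NA_real_, q, q))
  se <- sqrt(pmax(diag(vcov_th), 0))
  list(theta = theta, desc = desc, logl = st$logl, se = se, vcov = vcov_th,
       converged = converged, identifiable = identifiable, n_iter = iter,
       overlap_ok = overlap_ok)
}

## standard per-trait fixed-effect design: intercept + dataset when >1 label
.trait_design <- function(df) {
  if (!is.null(df$dataset) && length(unique(df$dataset)) > 1)
    stats::model.matrix(~ factor(dataset), df)
  else
    matrix(1, nrow(df), 1)
}

#' Fit GREML variance components
#'
#' @param data data frame of trait records with columns `animal_id`,
#'   `trait` (trait/cohort label), `y`, and optionally `dataset` (country of
#'   origin, fitted as a fixed effect within trait whenever more than one
#'   label is present). One record per animal per trait.
#' @param grm a [grm] covering every phenotyped animal.
#' @param overlap_min minimum number of animals carrying both traits for
#'   the residual covariance of a trait pair to be estimated; below this it
#'   is fixed at 0 (disjoint cohorts make it unidentifiable).
#' @param max_iter,tol_logl,tol_par optimizer controls: convergence when
#'   the log-likelihood changes by less than `tol_logl` and parameters by
#'   less than `tol_par` (relative).
#' @param eigen_cache optional pre-computed `eigen()` of the GRM (univariate
#'   fast path only).
#' @return object of class `varcomp`: `P` and `R` (T x T), `se_P`, `se_R`,
#'   `log_likelihood`, `n_iterations`, `converged`, `identifiable`,
#'   `traits`, and the parameter covariance for delta-method summaries.
#' @export
fit_greml <- function(data, grm, overlap_min = 30, max_iter = 60,
                      tol_logl = 1e-8, tol_par = 1e-6, eigen_cache = NULL) {
  stopifnot(inherits(grm, "grm"),
            all(c("animal_id", "trait", "y") %in% names(data)))
  traits <- unique(as.character(data$trait))
  Tn <- length(traits)
  if (Tn > 3) stop("at most three traits supported")
  miss <- setdiff(unique(data$animal_id), grm$animal_ids)
  if (length(miss))
    stop(length(miss), " phenotyped animal(s) absent from the GRM, e.g. ",
         miss[1])
  ylist <- list(); Xlist <- list(); aidx <- list()
  for (t in seq_len(Tn)) {
    df <- data[data$trait == traits[t], , drop = FALSE]
    if (anyDuplicated(df$animal_id))
      stop("more than one record per animal for trait '", traits[t], "'")
    ylist[[t]] <- df$y
    Xlist[[t]] <- .trait_design(df)
    aidx[[t]] <- match(df$animal_id, grm$animal_ids)
  }
  if (Tn == 1) {
    eig <- if (is.null(eigen_cache))
      .grm_eigen(grm$matrix[aidx[[1]], aidx[[1]]]) else eigen_cache
    fit <- .reml_uni(ylist[[1]], Xlist[[1]], eig, max_iter, tol_logl, tol_par)
    desc <- list(list(kind = "P", t1 = 1, t2 = 1),
                 list(kind = "R", t1 = 1, t2 = 1))
    theta <- fit$theta; se <- fit$se
  } else {
    if (!is.null(eigen_cache))
      warning("eigen_cache is only used in the univariate fast path")
    fit <- .reml_multi(ylist, Xlist, aidx, grm$matrix, overlap_min,
                       max_iter, tol_logl, tol_par)
    desc <- fit$desc; theta <- fit$theta; se <- fit$se
  }
  P <- matrix(0, Tn, Tn, dimnames = list(traits, traits))
  R <- se_P <- se_R <- P
  se_R[] <- NA
  for (j in seq_along(desc)) {
    d <- desc[[j]]
    if (d$kind == "P") {
      P[d$t1, d$t2] <- P[d$t2, d$t1] <- theta[j]
      se_P[d$t1, d$t2] <- se_P[d$t2, d$t1] <- se[j]
    } else {
      R[d$t1, d$t2] <- R[d$t2, d$t1] <- theta[j]
      se_R[d$t1, d$t2] <- se_R[d$t2, d$t1] <- se[j]
    }
  }
  structure(list(P = P, R = R, se_P = se_P, se_R = se_R,
                 log_likelihood = fit$logl, n_iterations = fit$n_iter,
                 converged = fit$converged, identifiable = fit$identifiable,
                 traits = traits, theta = theta, desc = desc,
                 vcov_theta = fit$vcov),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("GREML variance components (", length(x$traits), " trait(s); ",
      if (x$converged) "converged" else "NOT converged", " in ",
      x$n_iterations, " iterations)\n", sep = "")
  cat("P (genetic):\n"); print(round(x$P, 4))
  cat("R (residual):\n"); print(round(x$R, 4))
  invisible(x)
}

.theta_index <- function(vc, kind, t1, t2) {
  for (j in seq_along(vc$desc)) {
    d <- vc$desc[[j]]
    if (d$kind == kind && ((d$t1 == t1 && d$t2 == t2) ||
                           (d$t1 == t2 && d$t2 == t1))) return(j)
  }
  NA_integer_
}

#' Genomic heritability of a trait
#'
#' `h2 = P_tt / (P_tt + R_tt)` with a first-order delta-method standard
#' error from the inverse average-information matrix.
#'
#' @param vc a fitted [fit_greml()] object.
#' @param trait trait label or index (default first).
#' @return named vector `c(h2, se)`.
#' @export
heritability <- function(vc, trait = 1) {
  t <- if (is.character(trait)) match(trait, vc$traits) else trait
  vg <- vc$P[t, t]; ve <- vc$R[t, t]
  vp <- vg + ve
  if (vp <= 0) stop("zero phenotypic variance for trait ", trait)
  h2 <- vg / vp
  jg <- .theta_index(vc, "P", t, t); je <- .theta_index(vc, "R", t, t)
  se <- NA_real_
  if (!anyNA(vc$vcov_theta[c(jg, je), c(jg, je)])) {
    grad <- c(ve, -vg) / vp^2
    se <- sqrt(drop(t(grad) %*% vc$vcov_theta[c(jg, je), c(jg, je)] %*% grad))
  }
  c(h2 = h2, se = se)
}

#' Genetic correlation between two traits
#'
#' `rg = P_12 / sqrt(P_11 P_22)` with a delta-method standard error.
#' Returns `NaN` with an explanatory attribute when either genetic variance
#' is zero.
#'
#' @param vc a fitted [fit_greml()] object with T >= 2.
#' @param t1,t2 trait labels or indices.
#' @return named vector `c(rg, se)`.
#' @export
genetic_correlation <- function(vc, t1 = 1, t2 = 2) {
  a <- if (is.character(t1)) match(t1, vc$traits) else t1
  b <- if (is.character(t2)) match(t2, vc$traits) else t2
  p11 <- vc$P[a, a]; p22 <- vc$P[b, b]; p12 <- vc$P[a, b]
  if (p11 <= 1e-7 || p22 <= 1e-7) {
    out <- c(rg = NaN, se = NaN)
    attr(out, "reason") <- "zero genetic variance in at least one trait"
    return(out)
  }
  rg <- p12 / sqrt(p11 * p22)
  j <- c(.theta_index(vc, "P", a, a), .theta_index(vc, "P", a, b),
         .theta_index(vc, "P", b, b))
  se <- NA_real_
  if (!anyNA(vc$vcov_theta[j, j])) {
    grad <- c(-rg / (2 * p11), 1 / sqrt(p11 * p22), -rg / (2 * p22))
    se <- sqrt(drop(t(grad) %*% vc$vcov_theta[j, j] %*% grad))
  }
  c(rg = rg, se = se)
}

#' GBLUP breeding values, including unphenotyped validation animals
#'
#' Solves the mixed model at the supplied variance components and returns
#' GEBV for every animal in the GRM, for every trait. Records of masked
#' (validation) animals are removed from `y` before solving, so their GEBV
#' are predicted purely through genomic relationships.
#'
#' @param data trait records as for [fit_greml()].
#' @param grm a [grm] covering all animals (training and validation).
#' @param vc a fitted [fit_greml()] result (or compatible `P`/`R` list);
#'   an unconverged fit is refused unless `force = TRUE`.
#' @param mask animal ids whose phenotypes are withheld.
#' @param force allow prediction from an unconverged fit.
#' @return list with `gebv` (animals x traits matrix, rownames = animal
#'   ids), `fixed` (fixed-effect solutions per trait).
#' @export
predict_gebv <- function(data, grm, vc, mask = NULL, force = FALSE) {
  if (!isTRUE(vc$converged) && !force)
    stop("variance components did not converge; pass force = TRUE to override")
  traits <- vc$traits
  Tn <- length(traits)
  keep <- !(data$animal_id %in% mask)
  data <- data[keep & data$trait %in% traits, , drop = FALSE]
  ylist <- list(); Xlist <- list(); aidx <- list()
  for (t in seq_len(Tn)) {
    df <- data[data$trait == traits[t], , drop = FALSE]
    ylist[[t]] <- df$y
    Xlist[[t]] <- .trait_design(df)
    aidx[[t]] <- match(df$animal_id, grm$animal_ids)
    if (anyNA(aidx[[t]])) stop("record animal absent from GRM")
  }
  nrec <- vapply(ylist, length, 0L)
  offs <- cumsum(c(0L, nrec)); N <- sum(nrec)
  blk <- lapply(seq_len(Tn), function(t) (offs[t] + 1L):offs[t + 1L])
  G <- grm$matrix
  V <- matrix(0, N, N)
  for (a in seq_len(Tn)) for (b in a:Tn) {
    Vab <- vc$P[a, b] * G[aidx[[a]], aidx[[b]], drop = FALSE]
    V[blk[[a]], blk[[b]]] <- V[blk[[a]], blk[[b]]] + Vab
    if (a != b) V[blk[[b]], blk[[a]]] <- t(V[blk[[a]], blk[[b]]])
    if (a == b) {
      ii <- blk[[a]]
      V[cbind(ii, ii)] <- V[cbind(ii, ii)] + vc$R[a, a]
    } else if (vc$R[a, b] != 0) {
      common <- intersect(aidx[[a]], aidx[[b]])
      if (length(common)) {
        sh <- cbind(blk[[a]][match(common, aidx[[a]])],
                    blk[[b]][match(common, aidx[[b]])])
        V[sh] <- V[sh] + vc$R[a, b]
        V[sh[, 2:1, drop = FALSE]] <- V[sh[, 2:1, drop = FALSE]] + vc$R[a, b]
      }
    }
  }
  y <- unlist(ylist)
  X <- matrix(0, N, sum(vapply(Xlist, ncol, 0L)))
  cs <- cumsum(c(0L, vapply(Xlist, ncol, 0L)))
  for (t in seq_len(Tn)) X[blk[[t]], (cs[t] + 1L):cs[t + 1L]] <- Xlist[[t]]
  ch <- chol(V + diag(1e-10, N))
  Viy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  ViX <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
  bhat <- solve(crossprod(X, ViX), crossprod(ViX, y))
  r <- y - X %*% bhat
  Vir <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
  gebv <- matrix(0, nrow(G), Tn,
                 dimnames = list(grm$animal_ids, traits))
  for (t in seq_len(Tn)) for (b in seq_len(Tn))
    gebv[, t] <- gebv[, t] +
      vc$P[t, b] * (G[, aidx[[b]], drop = FALSE] %*% Vir[blk[[b]]])
  list(gebv = gebv, fixed = bhat)
}
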