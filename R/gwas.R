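#' Fit the GWAS null model and cache its spectral decomposition
#'
#' Univariate GREML fit of `y = Xb + g + e`, `g ~ N(0, sigma_g^2 G)`, by the
#' same REML machinery as [fit_greml()]; the eigendecomposition of the GRM
#' is cached so that each subsequent per-variant test costs O(n).
#'
#' @param data univariate trait records (`animal_id`, `y`, optional
#'   `dataset` fitted as a fixed effect).
#' @param grm a [grm] over (at least) the phenotyped animals.
#' @param eigen_cache optional pre-computed `eigen()` of the GRM restricted
#'   to the phenotyped animals (saves repeated decompositions when several
#'   traits share one GRM).
#' @return list of class `gwas_null`: variance components `vc`, whitening
#'   cache, the phenotyped animal ids, and the fixed-effect design.
#' @export
fit_null_model <- function(data, grm, eigen_cache = NULL) {
  stopifnot(all(c("animal_id", "y") %in% names(data)))
  data$trait <- "t1"
  aidx <- match(data$animal_id, grm$animal_ids)
  if (anyNA(aidx)) stop("phenotyped animal absent from GRM")
  eig <- if (is.null(eigen_cache)) .grm_eigen(grm$matrix[aidx, aidx])
         else eigen_cache
  vc <- fit_greml(data, grm, eigen_cache = eig)
  sg2 <- vc$P[1, 1]; se2 <- vc$R[1, 1]
  d <- sg2 * eig$values + se2
  ## whitened model: W y = W X b + W s alpha + eps, eps ~ N(0, I)
  W <- t(eig$vectors) / sqrt(d)            # rows scaled
  X <- .trait_design(data)
  Xw <- W %*% X
  qrx <- qr(Xw)
  list(vc = vc, sg2 = sg2, se2 = se2, eigen = eig, W = W,
       animal_ids = data$animal_id, y = data$y, X = X, Xw = Xw, qrx = qrx,
       yw = W %*% data$y)
}

#' Mixed-linear-model association scan
#'
#' Tests each variant, one at a time, as a covariate in the null mixed
#' model, with the null variance components held fixed (the standard
#' two-stage approximation). Effects and standard errors are generalised
#' least squares in the whitened model; the Wald test uses a t reference
#' with `n - rank(X) - 1` degrees of freedom and the signed t-value is
#' stored.
#'
#' @param g a [genotype_matrix]; only the null model's animals are used.
#' @param null a [fit_null_model()] result.
#' @param maf_min variants below this MAF (in the analysed animals) are
#'   excluded (default 0.01).
#' @param chunk variants per whitening block (memory control).
#' @return data frame of class `gwas_result`: `id`, `chrom`, `pos`, `maf`,
#'   `beta`, `se`, `t`, `p`, `n`, and a `skipped` attribute naming variants
#'   with no genotypic variance after whitening.
#' @export
mlm_scan <- function(g, null, maf_min = 0.01, chunk = 2000L) {
  ridx <- match(null$animal_ids, g$animal_ids)
  if (anyNA(ridx)) stop("null-model animal absent from genotypes")
  D <- impute_mean(g$dosages[ridx, , drop = FALSE])
  maf <- compute_maf(D)
  keep <- which(maf >= maf_min)
  n <- length(null$animal_ids)
  p_rank <- null$qrx$rank
  df <- n - p_rank - 1L
  Q <- qr.Q(null$qrx)
  yw <- null$yw
  yperp <- yw - Q %*% crossprod(Q, yw)
  yy <- sum(yperp^2)
  beta <- se <- tval <- rep(NA_real_, ncol(D))
  skipped <- character(0)
  for (start in seq(1L, length(keep), by = chunk)) {
    jj <- keep[start:min(start + chunk - 1L, length(keep))]
    Sw <- null$W %*% D[, jj, drop = FALSE]
    Sp <- Sw - Q %*% crossprod(Q, Sw)
    css <- colSums(Sp^2)
    good <- css > 1e-10
    b <- colSums(Sp * drop(yperp)) / pmax(css, 1e-300)
    rss <- pmax(yy - b^2 * css, 0)
    s2 <- rss / df
    sej <- sqrt(s2 / css)
    beta[jj[good]] <- b[good]
    se[jj[good]] <- sej[good]
    tval[jj[good]] <- (b / sej)[good]
    if (any(!good)) skipped <- c(skipped, g$variants$id[jj[!good]])
  }
  res <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos, maf = maf,
                    beta = beta, se = se, t = tval,
                    p = 2 * stats::pt(-abs(tval), df), n = n,
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$t), , drop = FALSE]
  attr(res, "skipped") <- skipped
  attr(res, "df") <- df
  class(res) <- c("gwas_result", class(res))
  res
}

#' Multi-trait meta-analysis chi-squared
#'
#' Combines per-variant signed t-values from T single-trait scans into
#' `chi2_i = t_i' V^-1 t_i`, where `V` is the T x T Pearson correlation
#' matrix of the signed t-vectors computed over all scanned variants;
#' p-values use the upper tail of the chi-squared distribution with T
#' degrees of freedom.
#'
#' @param t_matrix matrix of signed t-values, variants x traits (same
#'   variant set per trait; rownames carry variant ids).
#' @return data frame `id`, `chi2`, `p_meta`, with the correlation matrix
#'   `V` and degrees of freedom attached as attributes.
#' @export
meta_multitrait <- function(t_matrix) {
  t_matrix <- as.matrix(t_matrix)
  Tn <- ncol(t_matrix)
  if (Tn < 2) stop("need at least two traits")
  if (anyNA(t_matrix)) stop("signed t matrix contains NA")
  V <- stats::cor(t_matrix)
  off <- V[upper.tri(V)]
  if (any(abs(off) >= 0.999)) {
    warning("signed-t vectors nearly collinear; ridge 1e-6 added to V")
    V <- V + diag(1e-6, Tn)
  }
  Vi <- solve(V)
  chi2 <- rowSums((t_matrix %*% Vi) * t_matrix)
  out <- data.frame(id = if (!is.null(rownames(t_matrix)))
                      rownames(t_matrix) else seq_len(nrow(t_matrix)),
                    chi2 = chi2,
                    p_meta = stats::pchisq(chi2, df = Tn, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "V") <- V
  attr(out, "df") <- Tn
  out
}
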