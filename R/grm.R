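#' Genomic relationship matrix container
#'
#' @param matrix symmetric numeric matrix, animals x animals.
#' @param animal_ids character ids, one per row.
#' @param n_variants number of variants used to build the matrix.
#' @param maf_threshold MAF filter that was applied (or `NA`).
#' @return an object of class `grm`.
#' @export
new_grm <- function(matrix, animal_ids, n_variants = NA, maf_threshold = NA) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == ncol(matrix),
            nrow(matrix) == length(animal_ids))
  if (any(!is.finite(matrix))) stop("GRM entries must be finite")
  matrix <- (matrix + t(matrix)) / 2      # enforce exact symmetry
  dimnames(matrix) <- list(animal_ids, animal_ids)
  structure(list(matrix = matrix, animal_ids = as.character(animal_ids),
                 n_variants = n_variants, maf_threshold = maf_threshold),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "animals,", x$n_variants, "variants",
      "(mean diag ", round(mean(diag(x$matrix)), 3), ")\n")
  invisible(x)
}

#' MAF threshold guaranteeing at least 20 segregating allele copies
#'
#' Returns `10/n` clamped to `[0.01, 0.05]`, so that at least 20 copies of
#' the minor allele segregate in a sample of `n` diploid animals.
#'
#' @param n_animals sample size (>= 10).
#' @return minimum minor allele frequency to apply.
#' @export
effective_maf_threshold <- function(n_animals) {
  if (n_animals < 10) stop("need at least 10 animals")
  min(max(10 / n_animals, 0.01), 0.05)
}

#' Build a genomic relationship matrix by the method of Yang et al.
#'
#' Off-diagonals are `(1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2p_i(1-p_i))`;
#' diagonals use Yang's distinct estimator
#' `1 + (1/N) sum_i (x_ij^2 - (1+2p_i)x_ij + 2p_i^2) / (2p_i(1-p_i))`.
#' Allele frequencies are taken from the analysed sample. Missing dosages are
#' mean-imputed per variant on the fly. Variants below the MAF threshold are
#' excluded and counted.
#'
#' @param g a [genotype_matrix].
#' @param maf_min minimum minor allele frequency; `"auto"` applies
#'   [effective_maf_threshold()] for the sample size.
#' @return a [grm].
#' @export
build_grm_yang <- function(g, maf_min = "auto") {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  if (n < 2) stop("need at least 2 animals")
  if (identical(maf_min, "auto")) maf_min <- effective_maf_threshold(n)
  X <- impute_mean(g$dosages)
  p <- colMeans(X) / 2
  keep <- pmin(p, 1 - p) >= maf_min
  if (!any(keep)) stop("no variant passes the MAF filter (monomorphic input?)")
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  N <- ncol(X)
  w <- 1 / (2 * p * (1 - p))
  Z <- sweep(X, 2, 2 * p)                 # x - 2p
  Zw <- sweep(Z, 2, sqrt(w), `*`)
  G <- tcrossprod(Zw) / N
  ## Yang diagonal: 1 + mean_i (x^2 - (1+2p)x + 2p^2) * w
  dvals <- 1 + (X^2 %*% w - X %*% ((1 + 2 * p) * w) + sum(2 * p^2 * w)) / N
  diag(G) <- dvals
  new_grm(G, g$animal_ids, n_variants = N, maf_threshold = maf_min)
}

#' Aggregate two GRMs into a variance-weighted GRM
#'
#' `G_w = (var_a * G_a + var_b * G_b) / (var_a + var_b)`, the construction
#' used to merge an array-marker GRM with a selected-sequence-variant GRM,
#' weighting each by the genetic variance it explains.
#'
#' @param grm_a,grm_b [grm] objects over the same animals in the same order.
#' @param var_a,var_b non-negative weights (genetic variances); not both 0.
#' @return a [grm].
#' @export
combine_weighted_grm <- function(grm_a, grm_b, var_a, var_b) {
  if (!identical(grm_a$animal_ids, grm_b$animal_ids))
    stop("GRMs cover different animals (or different order)")
  if (var_a < 0 || var_b < 0) stop("weights must be non-negative")
  if (var_a + var_b == 0) stop("at least one weight must be positive")
  M <- (var_a * grm_a$matrix + var_b * grm_b$matrix) / (var_a + var_b)
  new_grm(M, grm_a$animal_ids,
          n_variants = sum(c(grm_a$n_variants, grm_b$n_variants), na.rm = TRUE))
}

#' Principal components of a GRM
#'
#' Top-`k` eigenpairs of the (optionally column/row-centered) GRM;
#' scores are `eigenvector * sqrt(eigenvalue)`.
#'
#' @param grm a [grm].
#' @param k number of components.
#' @param center double-center the matrix first (default TRUE).
#' @return list with `scores` (animals x k), `eigenvalues` (length k,
#'   non-increasing) and `animal_ids`.
#' @export
grm_pca <- function(grm, k = 2, center = TRUE) {
  M <- grm$matrix
  n <- nrow(M)
  if (k > n) stop("k exceeds the number of animals")
  if (center) {
    rm <- rowMeans(M)
    M <- M - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + mean(M)
  }
  e <- eigen(M, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(k)], 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  rownames(scores) <- grm$animal_ids
  list(scores = scores, eigenvalues = e$values[seq_len(k)],
       animal_ids = grm$animal_ids)
}

#' Pairwise population differentiation (G_ST and Hedrick's G'_ST)
#'
#' For each pair of groups and each variant, the within-group expected
#' heterozygosity is `H_S = mean_g 2 p_g (1-p_g)` and the total is
#' `H_T = 2 pbar (1-pbar)`. Multi-locus estimates use the ratio of sums,
#' `G_ST = sum(H_T - H_S) / sum(H_T)`; Hedrick's standardization (for k = 2
#' groups) is `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))` with `H_S`
#' the multi-locus mean.
#'
#' @param g a [genotype_matrix].
#' @param groups factor/character of group labels, one per animal.
#' @return list with symmetric zero-diagonal matrices `gst` and `gst_prime`.
#' @export
pairwise_fst <- function(g, groups) {
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 animals")
  X <- impute_mean(g$dosages)
  P <- vapply(labs, function(l) colMeans(X[groups == l, , drop = FALSE]) / 2,
              numeric(ncol(X)))          # variants x groups
  P <- matrix(P, ncol = length(labs), dimnames = list(NULL, labs))
  ngrp <- vapply(labs, function(l) sum(groups == l), 0L)
  k <- length(labs)
  gst <- gstp <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    p1 <- P[, a]; p2 <- P[, b]
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    poly <- ht > 0
    if (!any(poly)) stop("groups '", labs[a], "' and '", labs[b],
                         "' are monomorphic at every variant; FST undefined")
    g_st <- sum(ht[poly] - hs[poly]) / sum(ht[poly])
    hs_bar <- mean(hs[poly])
    denom <- (2 - 1) * (1 - hs_bar)
    g_stp <- if (denom <= 0) 1 else min(1, g_st * (2 - 1 + hs_bar) / denom)
    gst[a, b] <- gst[b, a] <- g_st
    gstp[a, b] <- gstp[b, a] <- g_stp
  }
  list(gst = gst, gst_prime = gstp)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining (via \pkg{ape}), returned as an unrooted
#' newick string. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving pairwise path
#' lengths through the parent node.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal.
#' @param labels tip labels (defaults to `rownames(d)`).
#' @return a newick string.
#' @export
nj_tree <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)
  tr <- ape::nj(stats::as.dist(d))
  ## clamp negative branches: move deficit to the sibling edge(s)
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    parent <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), i)
    deficit <- tr$edge.length[i]
    tr$edge.length[i] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::write.tree(tr)
}

#' Observed and predicted heterozygosities per group
#'
#' For each group: `HE_o` is the mean per-animal fraction of heterozygous
#' calls; `HE_oHW` is `sum 2 p_g (1-p_g) / N` from within-group frequencies;
#' `HE_pr = HE_base (1 - F)` where `HE_base` uses pooled frequencies and `F`
#' is the group's mean GRM diagonal minus 1 (inbreeding relative to the
#' pooled base population).
#'
#' @param g a [genotype_matrix].
#' @param grm the [grm] built over the same animals (same order).
#' @param groups group label per animal.
#' @return data frame with one row per group: `group`, `n`, `he_o`,
#'   `he_ohw`, `he_pr`, `f`.
#' @export
heterozygosity_report <- function(g, grm, groups) {
  groups <- as.character(groups)
  if (!identical(g$animal_ids, grm$animal_ids))
    stop("genotype and GRM animal sets differ")
  labs <- unique(groups)
  if (any(!table(factor(groups, labs)) > 0)) stop("empty group")
  X <- g$dosages
  p_all <- allele_freq(X)
  he_base <- mean(2 * p_all * (1 - p_all))
  het_animal <- rowMeans(X == 1, na.rm = TRUE)
  out <- lapply(labs, function(l) {
    idx <- which(groups == l)
    if (!length(idx)) stop("empty group: ", l)
    p_g <- allele_freq(X[idx, , drop = FALSE])
    f <- mean(diag(grm$matrix)[idx]) - 1
    data.frame(group = l, n = length(idx),
               he_o = mean(het_animal[idx]),
               he_ohw = mean(2 * p_g * (1 - p_g)),
               he_pr = he_base * (1 - f), f = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
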