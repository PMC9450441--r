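#' Cohort (birth-year) validation folds
#'
#' Validation-eligible animals are split into exactly four folds by year
#' of birth; trailing (most recent) years are merged down to four folds,
#' mirroring recording schemes where the last years are still small.
#' Animals without a birth year are retained in every training set
#' (`"train_only"`).
#'
#' @param animals data frame with `animal_id` and `birth_year`.
#' @param min_frac advisory minimum fold share of eligible animals; a
#'   fold below it triggers a warning (default 0.15).
#' @return data frame `animal_id`, `fold` (integer 1-4 or `"train_only"`).
#' @export
cohort_folds <- function(animals, min_frac = 0.15) {
  stopifnot(all(c("animal_id", "birth_year") %in% names(animals)))
  elig <- !is.na(animals$birth_year)
  yrs <- sort(unique(animals$birth_year[elig]))
  groups <- as.list(yrs)
  counts <- vapply(groups, function(g)
    sum(animals$birth_year %in% g, na.rm = TRUE), 0L)
  thresh <- min_frac * sum(elig)
  ## merge trailing (most recent) years down to exactly four folds;
  ## trailing years are the small ones in a growing recording scheme
  while (length(groups) > 4) {
    k <- length(groups)
    groups[[k - 1]] <- c(groups[[k - 1]], groups[[k]])
    counts[k - 1] <- counts[k - 1] + counts[k]
    groups <- groups[-k]; counts <- counts[-k]
  }
  if (length(groups) == 4 && min(counts) < thresh)
    warning("a cohort fold holds fewer than ", round(100 * min_frac),
            "% of eligible animals")
  if (length(groups) < 4)
    stop("fewer than 4 usable birth-year cohorts after merging")
  fold <- rep("train_only", nrow(animals))
  for (f in seq_along(groups))
    fold[animals$birth_year %in% groups[[f]]] <- as.character(f)
  data.frame(animal_id = animals$animal_id, fold = fold,
             stringsAsFactors = FALSE)
}

#' Sire-family validation folds
#'
#' Animals with unknown sires are retained in every training set; the rest
#' are split into `k` folds by dealing whole paternal half-sib families
#' (largest first, random tie order) to the currently smallest fold, so no
#' sire's offspring straddle folds.
#'
#' @param pedigree data frame with `animal_id` and `sire_id` (`NA` =
#'   unknown).
#' @param k number of folds (default 4).
#' @param seed integer seed for the family shuffle.
#' @return data frame `animal_id`, `fold`.
#' @export
sire_family_folds <- function(pedigree, k = 4, seed = 1L) {
  stopifnot(all(c("animal_id", "sire_id") %in% names(pedigree)))
  known <- !is.na(pedigree$sire_id)
  sires <- unique(pedigree$sire_id[known])
  if (length(sires) < k)
    stop("only ", length(sires), " sires; need at least ", k)
  set.seed(seed)
  fam_size <- table(pedigree$sire_id[known])[sires]
  ord <- sample(seq_along(sires))                    # random tie order
  sires <- sires[ord]; fam_size <- fam_size[ord]
  sires <- sires[order(-fam_size)]
  fold_of <- character(0)
  load <- rep(0L, k)
  for (s in sires) {
    f <- which.min(load)
    fold_of[s] <- as.character(f)
    load[f] <- load[f] + sum(pedigree$sire_id %in% s)
  }
  fold <- rep("train_only", nrow(pedigree))
  fold[known] <- fold_of[pedigree$sire_id[known]]
  data.frame(animal_id = pedigree$animal_id, fold = fold,
             stringsAsFactors = FALSE)
}

#' Accuracy of GEBV in a validation set
#'
#' The correlation between GEBV and the phenotype corrected for fixed
#' effects, divided by the square root of the genomic heritability of the
#' validation trait.
#'
#' @param gebv predicted breeding values of the validation animals.
#' @param corrected_pheno their fixed-effect-corrected phenotypes.
#' @param h2 genomic heritability used in the denominator (in (0, 1]).
#' @return accuracy (NA with a reason attribute if either vector is
#'   constant).
#' @export
gebv_accuracy <- function(gebv, corrected_pheno, h2) {
  stopifnot(length(gebv) == length(corrected_pheno), h2 > 0, h2 <= 1)
  if (length(gebv) < 10) stop("need at least 10 validation animals")
  if (stats::sd(gebv) == 0 || stats::sd(corrected_pheno) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance"
    return(out)
  }
  stats::cor(gebv, corrected_pheno) / sqrt(h2)
}

#' Dispersion bias of GEBV
#'
#' The ordinary-least-squares slope of the corrected phenotype on the GEBV;
#' 1 indicates neither inflation nor deflation.
#'
#' @inheritParams gebv_accuracy
#' @return regression slope.
#' @export
gebv_bias <- function(gebv, corrected_pheno) {
  if (stats::sd(gebv) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero GEBV variance"
    return(out)
  }
  stats::cov(corrected_pheno, gebv) / stats::var(gebv)
}

#' Summarise fold-level accuracies
#'
#' @param accuracies numeric vector of per-fold accuracies (must be 4
#'   unless `n_folds` overrides).
#' @param biases optional per-fold bias slopes.
#' @param n_folds expected number of folds.
#' @return list `mean_accuracy`, `se` (sample SD of the fold accuracies /
#'   sqrt(folds); flagged approximate because folds share training data),
#'   `mean_bias`, `per_fold`.
#' @export
summarize_folds <- function(accuracies, biases = NULL, n_folds = 4) {
  if (length(accuracies) != n_folds)
    stop("expected ", n_folds, " fold accuracies, got ", length(accuracies))
  out <- list(mean_accuracy = mean(accuracies),
              se = stats::sd(accuracies) / sqrt(n_folds),
              se_note = "approximate: folds share training animals",
              mean_bias = if (!is.null(biases)) mean(biases) else NA_real_,
              per_fold = data.frame(fold = seq_along(accuracies),
                                    accuracy = accuracies,
                                    bias = if (!is.null(biases)) biases
                                           else NA_real_))
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("mean accuracy %.3f (SE %.3f, approximate), mean bias %.3f\n",
              x$mean_accuracy, x$se, x$mean_bias))
  invisible(x)
}
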