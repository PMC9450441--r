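#' Describe a prediction scenario
#'
#' A scenario names the training composition (which country datasets
#' contribute records, and whether cohorts are treated as correlated traits
#' or merged into one standardised trait), the relationship-matrix kind,
#' and the cross-validation design. The validation population is always the
#' focal-country cohort of the first trait.
#'
#' @param name scenario label.
#' @param traits list of trait cohorts; each element is
#'   `list(name, datasets, column)` naming which datasets supply records
#'   for that trait and which phenotype column carries them. The first
#'   trait must contain `validation_dataset`.
#' @param validation_dataset dataset label of the validation population.
#' @param merged treat all listed cohorts as a single trait (each dataset
#'   standardised to zero mean / unit SD first).
#' @param grm_panel panel used for the GRM: `"array50k"`, `"hd"` or
#'   `"sequence"`.
#' @param weighted `NULL`, or a list describing GWAS-driven variant
#'   sharing: `discovery_datasets` (must exclude the validation dataset),
#'   `scan_columns` (phenotype columns scanned single-trait, then
#'   meta-combined), `set` (`"s1"`, `"s2"`, `"m"` or `"sm"`), and optional
#'   window parameters (`window_bp`, `slide_bp`, `top_k`, `p_max`).
#'   Alternatively `list(ids = ...)` supplies an already-selected variant
#'   set (e.g. from an external meta-analysis of summary statistics).
#' @param design `"cohort"` (birth-year folds) or `"random"` (sire-family
#'   folds).
#' @param fold_seed seed for the random fold design.
#' @param refit_vc re-estimate variance components per fold (default
#'   `FALSE`: they are estimated once on the scenario's training
#'   composition and treated as known across folds, which keeps desk-scale
#'   folds away from variance-collapse pathologies).
#' @return list of class `scenario`.
#' @export
scenario <- function(name,
                     traits = list(list(name = "focal", datasets = "P1",
                                        column = "y_trait1")),
                     validation_dataset = "P1",
                     merged = FALSE,
                     grm_panel = "array50k",
                     weighted = NULL,
                     design = "cohort",
                     fold_seed = 1L,
                     refit_vc = NULL) {
  if (!validation_dataset %in% traits[[1]]$datasets)
    stop("the first trait must contain the validation dataset")
  if (!is.null(weighted) && length(weighted$discovery_datasets) &&
      validation_dataset %in% weighted$discovery_datasets)
    stop("discovery GWAS must not include the validation population")
  structure(list(name = name, traits = traits,
                 validation_dataset = validation_dataset, merged = merged,
                 grm_panel = grm_panel, weighted = weighted, design = design,
                 fold_seed = fold_seed, refit_vc = refit_vc),
            class = "scenario")
}

## assemble fit_greml()-style records for one scenario from a bundle
.scenario_records <- function(sc, bundle) {
  an <- bundle$animals
  if (sc$merged) {
    all_ds <- unique(unlist(lapply(sc$traits, `[[`, "datasets")))
    rows <- do.call(rbind, lapply(sc$traits, function(tr) {
      df <- an[an$dataset %in% tr$datasets, , drop = FALSE]
      data.frame(animal_id = df$animal_id, dataset = df$dataset,
                 y = df[[tr$column]], stringsAsFactors = FALSE)
    }))
    rows <- rows[!duplicated(rows$animal_id), , drop = FALSE]
    rows$y <- standardise(rows$y, rows$dataset)
    rows$trait <- sc$traits[[1]]$name
    return(rows)
  }
  do.call(rbind, lapply(sc$traits, function(tr) {
    df <- an[an$dataset %in% tr$datasets, , drop = FALSE]
    data.frame(animal_id = df$animal_id, dataset = df$dataset,
               trait = tr$name, y = df[[tr$column]],
               stringsAsFactors = FALSE)
  }))
}

## discovery GWAS -> selected-variant ids (never sees validation phenotypes)
.weighted_selection <- function(sc, bundle, seq_panel) {
  w <- sc$weighted
  if (!is.null(w$ids))                  # pre-computed selection (already audited)
    return(structure(list(ids = w$ids,
                          provenance = list(precomputed = TRUE)),
                     class = "selection_set"))
  an <- bundle$animals
  disc <- an[an$dataset %in% w$discovery_datasets, , drop = FALSE]
  val_ids <- an$animal_id[an$dataset == sc$validation_dataset]
  if (length(intersect(disc$animal_id, val_ids)))
    stop("leakage: validation animals present in the discovery GWAS")
  gd <- seq_panel
  keep_an <- match(disc$animal_id, gd$animal_ids)
  gdisc <- genotype_matrix(gd$dosages[keep_an, , drop = FALSE],
                           disc$animal_id, gd$variants)
  mask <- filter_variants(gdisc$variants,
                          datasets = w$filter_datasets %||% c("ove", "aus"))
  gscan <- genotype_matrix(gdisc$dosages[, mask, drop = FALSE],
                           gdisc$animal_ids,
                           gdisc$variants[mask, , drop = FALSE])
  null_grm <- build_grm_yang(make_panel(gdisc, "hd"), maf_min = "auto")
  wp <- list(window_bp = w$window_bp %||% 1e5, slide_bp = w$slide_bp %||% 5e4,
             top_k = w$top_k %||% 3, p_max = w$p_max %||% 1e-3)
  eigc <- .grm_eigen(null_grm$matrix)
  scans <- lapply(w$scan_columns, function(col) {
    nd <- data.frame(animal_id = disc$animal_id, dataset = disc$dataset,
                     y = disc[[col]], stringsAsFactors = FALSE)
    null <- fit_null_model(nd, null_grm, eigen_cache = eigc)
    mlm_scan(gscan, null, maf_min = 0.01)
  })
  common <- Reduce(intersect, lapply(scans, `[[`, "id"))
  tmat <- vapply(scans, function(s) s$t[match(common, s$id)],
                 numeric(length(common)))
  rownames(tmat) <- common
  meta <- meta_multitrait(tmat)
  s_sets <- lapply(scans, function(s)
    do.call(select_top_windows, c(list(scan = s), wp)))
  meta_scan <- data.frame(id = meta$id,
                          chrom = gscan$variants$chrom[match(meta$id, gscan$variants$id)],
                          pos = gscan$variants$pos[match(meta$id, gscan$variants$id)],
                          p = meta$p_meta, t = sqrt(meta$chi2),
                          stringsAsFactors = FALSE)
  m_set <- do.call(select_top_windows, c(list(scan = meta_scan), wp))
  set <- switch(w$set %||% "sm",
                s1 = s_sets[[1]], s2 = s_sets[[2]], m = m_set,
                sm = combine_sets(c(s_sets, list(m_set)), name = "sm"))
  exclude_panel(set, bundle$genotypes$variants, "array50k")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one genomic-prediction scenario end to end
#'
#' Executes phenotype assembly, GRM construction (with optional
#' GWAS-driven weighted GRM whose discovery never touches validation
#' phenotypes), GREML, GBLUP prediction with per-fold masking, and
#' cross-validated accuracy/bias evaluation. Fold-level corrected
#' phenotypes subtract fixed effects estimated on the training fold only.
#' The heritability in the accuracy denominator is the genomic
#' heritability of the validation-population trait estimated once from the
#' array GRM on the full focal dataset (shared by every fold and
#' scenario, so comparisons between scenarios are unaffected by its
#' sampling noise).
#'
#' @param sc a [scenario()].
#' @param bundle a [simulate_bundle()] result (or an equivalent list with
#'   `genotypes`, `pedigree`, `animals`, `config`).
#' @param h2_floor lower bound applied to the per-fold heritability used in
#'   the accuracy denominator (numerical guard).
#' @return list with `report` (an `accuracy_report`), `vc`, `h2_folds`,
#'   `n_selected` (weighted scenarios), and a reproducibility `manifest`.
#' @export
run_scenario <- function(sc, bundle, h2_floor = 0.05) {
  stopifnot(inherits(sc, "scenario"))
  recs <- .scenario_records(sc, bundle)
  an <- bundle$animals
  val <- an[an$dataset == sc$validation_dataset, , drop = FALSE]
  folds <- if (sc$design == "cohort") cohort_folds(val)
           else sire_family_folds(val, seed = sc$fold_seed)
  used_ids <- unique(recs$animal_id)
  gsub_idx <- match(used_ids, bundle$genotypes$animal_ids)
  guse <- genotype_matrix(bundle$genotypes$dosages[gsub_idx, , drop = FALSE],
                          used_ids, bundle$genotypes$variants)
  grm_snp <- build_grm_yang(make_panel(guse, "array50k"), maf_min = "auto")
  n_selected <- NA_integer_
  if (is.null(sc$weighted)) {
    grm_main <- if (sc$grm_panel == "array50k") grm_snp
                else build_grm_yang(make_panel(guse, sc$grm_panel),
                                    maf_min = "auto")
  } else {
    sel <- .weighted_selection(sc, bundle, make_panel(bundle$genotypes,
                                                      "sequence"))
    n_selected <- length(sel$ids)
    keep <- match(sel$ids, guse$variants$id)
    keep <- keep[!is.na(keep)]
    if (!length(keep)) {
      warning("discovery GWAS selected no variants; using the array GRM")
      grm_main <- grm_snp
    } else {
      gsel <- genotype_matrix(guse$dosages[, keep, drop = FALSE], used_ids,
                              guse$variants[keep, , drop = FALSE])
      grm_seq <- build_grm_yang(gsel, maf_min = 0.01)
      ## genetic variance explained by each matrix, from the training records
      vc_snp <- fit_greml(.first_trait(recs), grm_snp)
      vc_seq <- fit_greml(.first_trait(recs), grm_seq)
      grm_main <- combine_weighted_grm(grm_snp, grm_seq,
                                       vc_snp$P[1, 1], vc_seq$P[1, 1])
    }
  }
  focal_trait <- recs$trait[match(TRUE, recs$dataset == sc$validation_dataset)]
  refit <- sc$refit_vc %||% FALSE
  vc_all <- if (refit) NULL else fit_greml(recs, grm_main)
  ## genomic h2 of the validation-population trait (array GRM, full focal
  ## dataset): the accuracy denominator, shared across folds and scenarios
  focal_all <- recs[recs$trait == focal_trait &
                      recs$dataset == sc$validation_dataset, , drop = FALSE]
  h2_denom <- unname(heritability(fit_greml(focal_all, grm_snp),
                                  focal_trait)["h2"])
  h2_denom <- min(max(h2_denom, h2_floor), 1)
  accs <- biases <- h2s <- numeric(0)
  for (f in as.character(1:4)) {
    vids <- folds$animal_id[folds$fold == f]
    train <- recs[!recs$animal_id %in% vids, , drop = FALSE]
    ftr <- train[train$trait == focal_trait &
                   train$dataset == sc$validation_dataset, , drop = FALSE]
    vc <- if (refit) fit_greml(train, grm_main) else vc_all
    pred <- predict_gebv(recs, grm_main, vc, mask = vids, force = TRUE)
    gv <- pred$gebv[vids, focal_trait]
    ## corrected phenotype: subtract training-fold fixed effects
    yv <- recs$y[match(vids, recs$animal_id)]
    fe_fit <- if (length(unique(ftr$dataset)) > 1)
      stats::lm(y ~ factor(dataset), ftr) else stats::lm(y ~ 1, ftr)
    corr <- yv - stats::predict(fe_fit, newdata = data.frame(
      dataset = rep(sc$validation_dataset, length(vids))))
    accs <- c(accs, gebv_accuracy(gv, corr, h2_denom))
    biases <- c(biases, gebv_bias(gv, corr))
    h2s <- c(h2s, h2_denom)
  }
  report <- summarize_folds(accs, biases)
  manifest <- list(scenario = sc$name, design = sc$design,
                   seed = bundle$config$seed,
                   config_hash = .config_hash(bundle$config),
                   n_training = nrow(recs), n_validation = nrow(folds),
                   grm = sc$grm_panel, weighted = !is.null(sc$weighted),
                   package = as.character(utils::packageVersion("rfigp")))
  list(report = report, vc = if (refit) NULL else vc_all, h2_folds = h2s,
       n_selected = n_selected, folds = folds, manifest = manifest)
}

.first_trait <- function(recs) {
  t1 <- recs$trait[1]
  recs[recs$trait == t1, , drop = FALSE]
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Accuracy differences against a baseline scenario
#'
#' Differences are reported in percentage points scaled by 100, i.e.
#' `100 * (accuracy_scenario - accuracy_baseline)`.
#'
#' @param reports named list of `run_scenario()` results (or
#'   `accuracy_report`s).
#' @param baseline name of the baseline entry.
#' @return data frame `scenario`, `accuracy`, `difference`.
#' @export
report_difference <- function(reports, baseline) {
  if (!baseline %in% names(reports)) stop("baseline '", baseline,
                                          "' not among the reports")
  get_acc <- function(r) if (!is.null(r$report)) r$report$mean_accuracy
                         else r$mean_accuracy
  acc <- vapply(reports, get_acc, 0)
  data.frame(scenario = names(reports), accuracy = acc,
             difference = 100 * (acc - acc[[baseline]]),
             row.names = NULL, stringsAsFactors = FALSE)
}
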