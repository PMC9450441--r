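#' Filter sequence variants on imputation quality and MAF
#'
#' A variant is removed if its imputation R2 is less than or equal to
#' `r2_min` in *both* of the two named datasets, or if its minor allele
#' frequency in the discovery dataset is less than or equal to `maf_min`
#' (both inequalities are strict removals at the boundary).
#'
#' @param variants variant table with per-dataset `r2_<label>` columns and
#'   `maf`.
#' @param datasets the two dataset labels whose R2 columns are consulted.
#' @param r2_min imputation-quality threshold (default 0.4).
#' @param maf_min MAF threshold (default 0.006).
#' @return logical mask of retained variants.
#' @export
filter_variants <- function(variants, datasets = c("ove", "aus"),
                            r2_min = 0.4, maf_min = 0.006) {
  cols <- paste0("r2_", datasets)
  miss <- setdiff(cols, names(variants))
  if (length(miss))
    stop("variant table lacks imputation-quality column(s): ",
         paste(miss, collapse = ", "))
  r2 <- as.matrix(variants[, cols, drop = FALSE])
  keep_r2 <- apply(r2 > r2_min, 1, any)       # removed only if poor in both
  keep_maf <- variants$maf > maf_min
  keep_r2 & keep_maf
}

#' Select top associated variants in sliding windows
#'
#' Windows of `window_bp` slide by `slide_bp` from position 0 along each
#' chromosome (half-open intervals `[start, start + window_bp)`). Within
#' each window, up to `top_k` variants with p-value below `p_max` are taken
#' in order of ascending p (ties broken by larger `|t|`, then lower
#' position); the union over windows is deduplicated.
#'
#' @param scan a scan result with `id`, `chrom`, `pos`, `p` and optionally
#'   `t` (use `chi2` scans via `p = p_meta`, `t = sqrt(chi2)`).
#' @param window_bp,slide_bp window geometry (defaults 100 kb / 50 kb).
#' @param top_k maximum variants per window (default 3).
#' @param p_max significance ceiling (default 1e-3).
#' @return object of class `selection_set`: list with `ids` and
#'   `provenance`.
#' @export
select_top_windows <- function(scan, window_bp = 100000, slide_bp = 50000,
                               top_k = 3, p_max = 1e-3) {
  stopifnot(all(c("id", "chrom", "pos", "p") %in% names(scan)))
  scan$.tie <- if (is.null(scan$t)) 0 else abs(scan$t)
  sel <- character(0)
  for (cc in unique(scan$chrom)) {
    sub <- scan[scan$chrom == cc & scan$p < p_max, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$p, -sub$.tie, sub$pos), , drop = FALSE]
    maxpos <- max(sub$pos)
    starts <- seq(0, maxpos, by = slide_bp)
    for (s in starts) {
      inw <- which(sub$pos >= s & sub$pos < s + window_bp)
      if (length(inw)) sel <- c(sel, sub$id[inw[seq_len(min(top_k, length(inw)))]])
    }
  }
  structure(list(ids = unique(sel),
                 provenance = list(window_bp = window_bp, slide_bp = slide_bp,
                                   top_k = top_k, p_max = p_max,
                                   n_scanned = nrow(scan))),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat("selection_set:", length(x$ids), "variants\n")
  invisible(x)
}

#' Union of selection sets
#'
#' @param ... selection sets (or a single list of them).
#' @param name optional name for the combined set.
#' @return a `selection_set` with deduplicated ids and concatenated
#'   provenance.
#' @export
combine_sets <- function(..., name = "combined") {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "selection_set"))
    sets <- sets[[1]]
  if (!length(sets)) stop("need at least one set")
  ids <- unique(unlist(lapply(sets, `[[`, "ids")))
  structure(list(ids = ids, name = name,
                 provenance = lapply(sets, `[[`, "provenance")),
            class = "selection_set")
}

#' Drop variants already present on a panel
#'
#' Selected sequence variants intended for a weighted GRM exclude variants
#' that are already on the array panel.
#'
#' @param set a `selection_set`.
#' @param variants variant table with `id` and `panel_<panel>` flags.
#' @param panel panel label (default `"array50k"`).
#' @return the filtered `selection_set`.
#' @export
exclude_panel <- function(set, variants, panel = "array50k") {
  col <- paste0("panel_", panel)
  if (is.null(variants[[col]])) stop("unknown panel: ", panel)
  on_panel <- variants$id[variants[[col]]]
  set$ids <- setdiff(set$ids, on_panel)
  set$provenance <- c(set$provenance, list(excluded_panel = panel))
  set
}
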