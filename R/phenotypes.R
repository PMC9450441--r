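#' Energy-corrected milk
#'
#' `ECM = 0.1 * milk + 5.2 * fat + 2.6 * protein`, all in kg/day.
#'
#' @param milk,fat,protein daily yields (kg/day), non-negative.
#' @return ECM in kg/day.
#' @export
compute_ecm <- function(milk, fat, protein) {
  if (any(c(milk, fat, protein) < 0, na.rm = TRUE))
    stop("yields must be non-negative")
  0.1 * milk + 5.2 * fat + 2.6 * protein
}

#' Orthogonal polynomial basis
#'
#' Columns are mutually orthogonal, unit-norm, and orthogonal to the
#' constant (the basis of centered monomials after Gram-Schmidt, as
#' produced by [stats::poly()]); the constant column is excluded.
#'
#' @param x numeric covariate.
#' @param degree polynomial degree (>= 1); needs more than `degree`
#'   distinct values.
#' @return matrix with `degree` columns.
#' @export
orthogonal_poly <- function(x, degree) {
  if (degree < 1) stop("degree must be >= 1")
  if (length(unique(x)) <= degree)
    stop("need more than ", degree, " distinct values for a degree-",
         degree, " orthogonal polynomial")
  unclass(stats::poly(x, degree = degree))[, , drop = FALSE]
}

#' Daily body-weight change from repeated weights
#'
#' Fits a fifth-order orthogonal-polynomial regression of body weight on
#' days in milk (records restricted to DIM 5-306) and returns, for each
#' record's day `d`, the difference in predicted BW between day `d` and day
#' `d - 1`.
#'
#' @param dim days in milk per record.
#' @param bw body weight per record (kg).
#' @param degree polynomial degree (default 5).
#' @param min_records,min_span minimum number of records and DIM span
#'   required; below these every record gets `NA` (the animal is dropped
#'   from RFI later).
#' @return numeric vector of daily BW change (kg/day), one per record.
#' @export
compute_delta_bw <- function(dim, bw, degree = 5, min_records = 7,
                             min_span = 30) {
  keep <- dim >= 5 & dim <= 306 & !is.na(bw)
  out <- rep(NA_real_, length(dim))
  if (sum(keep) < min_records) return(out)
  d <- dim[keep]; w <- bw[keep]
  if (diff(range(d)) < min_span || length(unique(d)) <= degree) return(out)
  fit <- stats::lm(w ~ stats::poly(d, degree = degree, raw = FALSE))
  pred <- function(day) {
    B <- stats::predict(fit, newdata = data.frame(d = day))
    B
  }
  out[keep] <- pred(d) - pred(d - 1)
  out
}

#' Describe an RFI adjustment model
#'
#' @param fixed_factors names of categorical fixed-effect columns (e.g.
#'   contemporary group, parity, parityST, HYS, trial).
#' @param covariates names of numeric covariate columns (e.g. DIM, ECM,
#'   MBW, dBW).
#' @param polynomial named integer vector: covariates to expand as
#'   orthogonal polynomials of the given degree (e.g. `c(age = 2)`).
#' @return list of class `rfi_model_spec`.
#' @export
rfi_model_spec <- function(fixed_factors = c("cgroup", "parity"),
                           covariates = c("dim", "ecm", "mbw", "dbw"),
                           polynomial = NULL) {
  structure(list(fixed_factors = fixed_factors, covariates = covariates,
                 polynomial = polynomial), class = "rfi_model_spec")
}

#' The lactating-cow RFI model (contemporary group + DIM + parity +
#' ECM + MBW + dBW)
#' @return an [rfi_model_spec()].
#' @export
rfi_spec_cow <- function() {
  rfi_model_spec(fixed_factors = c("cgroup", "parity"),
                 covariates = c("dim", "ecm", "mbw", "dbw"))
}

#' The overseas-cow RFI model (parity-stage + HYS + trial + DIM +
#' quadratic age polynomial + ECM + MBW + dBW)
#' @return an [rfi_model_spec()].
#' @export
rfi_spec_overseas <- function() {
  rfi_model_spec(fixed_factors = c("parityst", "hys", "trial"),
                 covariates = c("dim", "ecm", "mbw", "dbw"),
                 polynomial = c(age = 2))
}

#' Add the parity-by-lactation-stage factor
#'
#' Parity collapsed to 3 levels (1, 2, 3+) crossed with four stages of
#' lactation (<=30, 31-100, 101-200, >200 DIM).
#'
#' @param records data frame with `parity` and `dim`.
#' @return the records with a `parityst` column added.
#' @export
add_parityst <- function(records) {
  pl <- pmin(records$parity, 3)
  stage <- cut(records$dim, c(-Inf, 30, 100, 200, Inf),
               labels = c("st1", "st2", "st3", "st4"))
  records$parityst <- paste0("p", pl, ":", stage)
  records
}

#' Derive residual feed intake
#'
#' Ordinary-least-squares fit of DMI on the model's fixed factors and
#' covariates; RFI is the residual, averaged per animal when an animal has
#' several records. Records with missing covariates are dropped before
#' fitting. Factors with fewer than 2 observed levels are dropped with a
#' warning. The mean residual over fitted records is zero by construction.
#'
#' @param records data frame of per-record phenotypes including `animal_id`
#'   and `dmi`.
#' @param spec an [rfi_model_spec()].
#' @return data frame with one row per retained animal: `animal_id`,
#'   `dataset` (if present), `n_records`, `rfi`. The per-record residuals
#'   are attached as attribute `"record_rfi"`.
#' @export
derive_rfi <- function(records, spec = rfi_spec_cow()) {
  stopifnot(inherits(spec, "rfi_model_spec"))
  need <- c("animal_id", "dmi", spec$fixed_factors, spec$covariates,
            names(spec$polynomial))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  covs <- c(spec$covariates, names(spec$polynomial))
  ok <- stats::complete.cases(records[, c("dmi", covs), drop = FALSE])
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no complete records to fit")
  terms <- character(0)
  for (f in spec$fixed_factors) {
    if (length(unique(rec[[f]])) < 2) {
      warning("factor '", f, "' has a single observed level; dropped")
    } else terms <- c(terms, sprintf("factor(%s)", f))
  }
  terms <- c(terms, spec$covariates)
  for (v in names(spec$polynomial))
    terms <- c(terms, sprintf("orthogonal_poly(%s, %d)", v,
                              spec$polynomial[[v]]))
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = "dmi")
  fit <- stats::lm(fml, data = rec)
  res <- stats::residuals(fit)
  agg <- stats::aggregate(res, by = list(animal_id = rec$animal_id), FUN = mean)
  out <- data.frame(animal_id = agg$animal_id, rfi = agg$x,
                    stringsAsFactors = FALSE)
  nr <- table(rec$animal_id)
  out$n_records <- as.integer(nr[out$animal_id])
  if (!is.null(rec$dataset)) {
    ds <- rec$dataset[!duplicated(rec$animal_id)]
    names(ds) <- rec$animal_id[!duplicated(rec$animal_id)]
    out$dataset <- ds[out$animal_id]
  }
  out <- out[, c("animal_id", if (!is.null(out$dataset)) "dataset",
                 "n_records", "rfi")]
  attr(out, "record_rfi") <- res
  attr(out, "fit") <- fit
  out
}

#' Standardise values to z-scores, optionally within groups
#'
#' `(x - mean) / SD` with the sample SD (n - 1 denominator), applied within
#' each group (dataset/country) before pooling.
#'
#' @param x numeric values.
#' @param group optional group label per value.
#' @return z-scores.
#' @export
standardise <- function(x, group = NULL) {
  if (is.null(group)) group <- rep("all", length(x))
  out <- x
  for (lab in unique(group)) {
    idx <- which(group == lab)
    s <- stats::sd(x[idx])
    if (!is.finite(s) || s == 0)
      stop("zero variance in dataset '", lab, "'; cannot standardise")
    out[idx] <- (x[idx] - mean(x[idx])) / s
  }
  out
}
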