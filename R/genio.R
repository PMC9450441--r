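#' Construct a genotype matrix container
#'
#' Bundles a dosage matrix (animals x variants, counting copies of the A1
#' allele, coded 0/1/2 with `NA` for missing) with its animal ids and a
#' variant metadata table.
#'
#' @param dosages integer matrix, animals in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param animal_ids character vector, one id per row of `dosages`.
#' @param variants data frame with one row per column of `dosages`. Must
#'   contain `id`, `chrom` and `pos` (1-based); `ref`/`alt` alleles, per-panel
#'   membership flags (`panel_*` logical columns) and per-dataset imputation
#'   quality (`r2_*` columns) are carried along when present. A `maf` column
#'   is (re)computed from the dosages.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `animal_ids`, `variants`.
#' @export
genotype_matrix <- function(dosages, animal_ids, variants) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(animal_ids))
    stop("dosages has ", nrow(dosages), " rows but ", length(animal_ids),
         " animal ids")
  if (ncol(dosages) != nrow(variants))
    stop("dosages has ", ncol(dosages), " columns but variants has ",
         nrow(variants), " rows")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing dosages must be 0, 1 or 2")
  for (col in c("id", "chrom", "pos"))
    if (is.null(variants[[col]])) stop("variants lacks required column '", col, "'")
  rownames(dosages) <- animal_ids
  colnames(dosages) <- variants$id
  variants$maf <- compute_maf(dosages)
  structure(list(dosages = dosages,
                 animal_ids = as.character(animal_ids),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$animal_ids), "animals x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency per variant
#'
#' @param dosages dosage matrix (0/1/2/NA), animals x variants.
#' @return numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @export
compute_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' A1 allele frequency per variant (from non-missing calls)
#' @noRd
allele_freq <- function(dosages) colMeans(dosages, na.rm = TRUE) / 2

#' Mean-impute missing dosages per variant
#'
#' Missing entries are replaced by twice the A1 allele frequency of the
#' variant (its per-variant mean dosage). Raw stored genotypes are never
#' modified; this is applied on the fly at GRM/GWAS time.
#'
#' @param dosages dosage matrix with possible `NA`s.
#' @return numeric matrix without `NA`s.
#' @export
impute_mean <- function(dosages) {
  miss <- which(is.na(dosages))
  if (!length(miss)) return(dosages * 1.0)
  mu <- colMeans(dosages, na.rm = TRUE)
  dosages[miss] <- mu[((miss - 1L) %/% nrow(dosages)) + 1L]
  dosages
}

## ---- PLINK bed/bim/fam ----

## 2-bit codes (per pair of bits, low bits first sample):
## 00 -> hom A1 (dosage 2), 01 -> missing, 10 -> het, 11 -> hom A2 (dosage 0)
.bed_decode_table <- local({
  dec <- c(2L, NA, 1L, 0L)
  tab <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255)
    tab[b + 1L, ] <- dec[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  tab
})

#' Read a PLINK binary genotype triplet
#'
#' Reads `<prefix>.bed` (v1.00, SNP-major), `<prefix>.bim` and
#' `<prefix>.fam`. Dosages count copies of the A1 allele as stored; no
#' frequency-based allele flipping is performed.
#'
#' @param prefix path prefix of the bed/bim/fam triplet.
#' @return a [genotype_matrix].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  names(bim_df) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  n <- nrow(fam_df); m <- nrow(bim_df)
  bpv <- (n + 3L) %/% 4L
  raw <- readBin(bed, "raw", n = 3L + m * bpv + 1L)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed (v1.00) supported: ", bed)
  body <- raw[-(1:3)]
  if (length(body) != m * bpv)
    stop("bed file '", bed, "' has ", length(body),
         " genotype bytes; expected ", m * bpv, " for ", n, " animals x ",
         m, " variants")
  dec <- .bed_decode_table[as.integer(body) + 1L, , drop = FALSE]
  x <- t(dec)                              # 4 x (bpv*m), variant-major
  dim(x) <- c(4L * bpv, m)
  dos <- x[seq_len(n), , drop = FALSE]
  variants <- data.frame(id = bim_df$id, chrom = bim_df$chrom, pos = bim_df$pos,
                         ref = bim_df$a2, alt = bim_df$a1,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, as.character(fam_df[[2]]), variants)
}

#' Write a PLINK binary genotype triplet
#'
#' @param g a [genotype_matrix].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  fam <- data.frame(fid = g$animal_ids, iid = g$animal_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  v <- g$variants
  ref <- if (is.null(v$ref)) rep("A", m) else v$ref
  alt <- if (is.null(v$alt)) rep("B", m) else v$alt
  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos,
                    a1 = alt, a2 = ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  ## dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, nrow = 4L * ((n + 3L) %/% 4L), ncol = m)
  d <- g$dosages
  cmap <- function(dd) ifelse(is.na(dd), 1L, c(3L, 2L, 0L)[dd + 1L])
  code[seq_len(n), ] <- cmap(d)
  code[seq_len(nrow(code)) > n, ] <- 0L     # pad bits zero
  dim(code) <- c(4L, length(code) %/% 4L)
  bytes <- as.raw(code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] + 64L * code[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

## ---- GRM binary triplet (float32 lower triangle) ----

#' Write a GRM in the binary triplet convention
#'
#' Writes `<prefix>.grm.bin` (float32 lower triangle including the diagonal,
#' rows `j = 1..n`, columns `k = 1..j`), `<prefix>.grm.id` (two-column id
#' text) and `<prefix>.grm.N.bin` (float32 number of variants per pair).
#'
#' @param grm a [grm] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_binary <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  M <- grm$matrix
  if (max(abs(M - t(M))) > 0) stop("GRM must be symmetric")
  n <- nrow(M)
  lt <- M[upper.tri(M, diag = TRUE)]       # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb"); writeBin(lt, con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_variants), length(lt)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(grm$animal_ids, grm$animal_ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GRM from the binary triplet convention
#'
#' @param prefix path prefix of the `.grm.bin`/`.grm.id`/`.grm.N.bin` triplet.
#' @return a [grm] object (float32 precision).
#' @export
read_grm_binary <- function(prefix) {
  idf <- paste0(prefix, ".grm.id"); binf <- paste0(prefix, ".grm.bin")
  for (f in c(idf, binf)) if (!file.exists(f)) stop("missing file: ", f)
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  want <- n * (n + 1L) / 2
  lt <- readBin(binf, "numeric", n = want + 1L, size = 4L)
  if (length(lt) != want)
    stop("GRM binary '", binf, "' holds ", length(lt),
         " entries; id file implies ", want)
  M <- matrix(0, n, n)
  M[upper.tri(M, diag = TRUE)] <- lt
  M <- M + t(M) - diag(diag(M))
  nb <- paste0(prefix, ".grm.N.bin")
  nv <- if (file.exists(nb)) round(readBin(nb, "numeric", n = 1L, size = 4L)) else NA
  new_grm(M, ids, n_variants = nv)
}

## ---- phenotype tables ----

#' Read a delimited phenotype table
#'
#' Accepts tab- or comma-delimited text with a header row. Required columns
#' are checked by name; numeric columns are parsed strictly (a non-numeric
#' entry is an error naming the offending row). Unknown sires (empty, `NA`
#' or `0`) are encoded as `NA`, distinct from any real id.
#'
#' @param path file path.
#' @param required character vector of required column names
#'   (default: the core animal/trait schema).
#' @param numeric_cols columns parsed as numeric when present.
#' @return a data frame with one row per record.
#' @export
read_phenotypes <- function(path,
                            required = c("animal_id", "dataset"),
                            numeric_cols = c("birth_year", "dim", "parity",
                                             "milk", "fat", "protein", "bw",
                                             "dmi", "age", "ecm", "mbw",
                                             "dbw", "rfi")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(df$sire_id)) {
    s <- as.character(df$sire_id)
    s[s %in% c("0", "NA", "")] <- NA
    df$sire_id <- s
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw_v <- df[[col]]
    num <- suppressWarnings(as.numeric(raw_v))
    bad <- which(is.na(num) & !is.na(raw_v))
    if (length(bad))
      stop("column '", col, "' of '", path, "' is not numeric at row ",
           bad[1], " (value '", raw_v[bad[1]], "')")
    df[[col]] <- num
  }
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Write a phenotype table as tab-delimited text
#' @param df data frame of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
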