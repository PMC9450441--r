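#' Configuration for the synthetic multi-country cattle generator
#'
#' Defaults emulate a Holstein-like multi-country feed-efficiency study at
#' desk scale: several mildly differentiated country groups (Balding-Nichols
#' drift on a shared base population), paternal half-sib families, a
#' sequence-density variant set with a 50k-like array subset that excludes
#' the causal variants, moderate heritability, and a high genetic
#' correlation between the country-specific expressions of the trait.
#'
#' @param n_countries number of country groups.
#' @param animals_per_country animals simulated per country (recycled).
#' @param n_sires_per_country sires per country; offspring are assigned to
#'   sires uniformly, giving paternal half-sib families.
#' @param prop_unknown_sire fraction of animals with unrecorded sire.
#' @param n_chrom,chrom_length_bp genome layout.
#' @param n_sequence_variants total sequence-density variants.
#' @param array_fraction fraction of common (MAF >= 0.05) variants placed on
#'   the array panel.
#' @param n_qtl number of causal variants (drawn from the sequence set).
#' @param qtl_maf_min minimum MAF of causal variants (default 0.05: common
#'   causal alleles, well tagged by surrounding markers, as for a breed
#'   with long-range LD).
#' @param qtl_on_array if `FALSE` (default) causal variants are excluded
#'   from the array panel.
#' @param h2 per-trait heritability vector (length T, each in (0,1)). The
#'   default three traits play the roles of: RFI measured in the focal
#'   (validation) country, RFI measured overseas (genetic correlation 0.95
#'   with the focal expression), and DMI measured overseas.
#' @param rg T x T genetic correlation matrix (unit diagonal, PSD).
#' @param country_fst per-country Balding-Nichols drift parameter.
#' @param n_founder_hap founder haplotypes in the shared pool; controls
#'   the effective number of independent chromosome segments and hence
#'   baseline GBLUP accuracy.
#' @param n_ancestral_hap ancestral haplotypes from which the founders are
#'   built as fine-grained mosaics; controls local linkage disequilibrium
#'   (how well nearby markers tag a causal variant).
#' @param founder_block_rate expected ancestral crossovers per chromosome
#'   when building a founder haplotype (sets the local LD block length).
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @param rfi_record_noise within-animal record noise (kg/day) on the DMI
#'   equation; set to 0 for a noise-free recovery problem.
#' @param rfi_sd phenotypic SD (kg/day) of the injected per-animal RFI in
#'   the DMI equation (the trait columns `y_trait*` stay standardised).
#' @param trait_blocks integer label per trait; traits in the same block
#'   are expressions of the same biological trait and always share causal
#'   variants (default: one block, i.e. fully pleiotropic traits, the
#'   regime of feed-intake traits that are components of each other).
#' @param pleiotropy_frac probability that a causal variant affects every
#'   block; otherwise it is private to one randomly chosen block. Sparse
#'   pleiotropy makes single-trait and meta-analysis scans genuinely
#'   complementary.
#' @param seed mandatory integer seed; the same seed reproduces the same
#'   data byte for byte.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_countries = 7,
                       animals_per_country = c(400, rep(150, 6)),
                       n_sires_per_country = c(50, rep(20, 6)),
                       prop_unknown_sire = 0.10,
                       n_chrom = 5,
                       chrom_length_bp = 1e7,
                       n_sequence_variants = 12000,
                       array_fraction = 0.50,
                       n_qtl = 100,
                       qtl_maf_min = 0.05,
                       qtl_on_array = FALSE,
                       h2 = c(0.30, 0.30, 0.33),
                       rg = matrix(c(1, 0.95, 0.50,
                                     0.95, 1, 0.60,
                                     0.50, 0.60, 1), 3),
                       country_fst = rep(0.01, n_countries),
                       n_founder_hap = 600,
                       n_ancestral_hap = 60,
                       founder_block_rate = 150,
                       crossover_rate = 1,
                       rfi_record_noise = 0.5,
                       rfi_sd = 1.3,
                       trait_blocks = NULL,
                       pleiotropy_frac = 0.5,
                       seed = 1L) {
  T_ <- length(h2)
  rg <- as.matrix(rg)
  if (nrow(rg) != T_ || ncol(rg) != T_)
    stop("rg must be ", T_, "x", T_, " to match h2")
  if (max(abs(rg - t(rg))) > 1e-12 || any(abs(diag(rg) - 1) > 1e-12))
    stop("rg must be symmetric with unit diagonal")
  if (min(eigen(rg, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("rg must be positive semi-definite")
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie strictly in (0, 1)")
  if (array_fraction <= 0 || array_fraction >= 1)
    stop("array_fraction must lie in (0, 1)")
  if (n_qtl > n_sequence_variants)
    stop("n_qtl exceeds the number of sequence variants")
  if (is.null(trait_blocks)) trait_blocks <- rep(1L, T_)
  if (length(trait_blocks) != T_) stop("trait_blocks must have one label per trait")
  country_fst <- rep_len(country_fst, n_countries)
  animals_per_country <- rep_len(animals_per_country, n_countries)
  n_sires_per_country <- rep_len(n_sires_per_country, n_countries)
  structure(as.list(environment()), class = "sim_config")
}

## ancestral haplotypes for one chromosome: alleles are assigned to the
## clades of a random-join genealogy, so nearby variants carried by the
## same or nested clades are strongly correlated (mutation-on-genealogy LD)
.ancestral_chrom <- function(K0, p_targets) {
  act <- as.list(seq_len(K0))
  clades <- act
  while (length(act) > 1) {
    i <- sample.int(length(act), 2)
    merged <- c(act[[i[1]]], act[[i[2]]])
    act <- c(act[-i], list(merged))
    clades <- c(clades, list(merged))
  }
  sizes <- vapply(clades, length, 0L)
  keep <- sizes < K0
  clades <- clades[keep]; sizes <- sizes[keep]
  H <- matrix(0L, K0, length(p_targets))
  for (j in seq_along(p_targets)) {
    w <- exp(-3 * abs(sizes - p_targets[j] * K0))
    cl <- clades[[sample.int(length(clades), 1L, prob = w)]]
    H[cl, j] <- 1L
  }
  H
}

## one gamete as a mosaic over a founder haplotype pool, haplotypes drawn
## with country-specific weights
.mosaic_gamete <- function(pool, chrom_ranges, rate, w = NULL) {
  m <- ncol(pool)
  gam <- integer(m)
  for (r in chrom_ranges) {
    lo <- r[1]; hi <- r[2]; len <- hi - lo + 1L
    k <- stats::rpois(1, rate)
    bp <- sort(sample.int(len - 1L, min(k, len - 1L)))
    starts <- c(lo, lo + bp); ends <- c(lo + bp - 1L, hi)
    hap <- sample.int(nrow(pool), length(starts), replace = TRUE, prob = w)
    for (s in seq_along(starts))
      gam[starts[s]:ends[s]] <- pool[hap[s], starts[s]:ends[s]]
  }
  gam
}

## meiosis: recombine an individual's two gametes
.meiosis <- function(h1, h2, chrom_ranges, rate) {
  gam <- integer(length(h1))
  hh <- rbind(h1, h2)
  for (r in chrom_ranges) {
    lo <- r[1]; hi <- r[2]; len <- hi - lo + 1L
    k <- stats::rpois(1, rate)
    bp <- sort(sample.int(len - 1L, min(k, len - 1L)))
    starts <- c(lo, lo + bp); ends <- c(lo + bp - 1L, hi)
    phase <- (sample.int(2L, 1L) + seq_along(starts) - 2L) %% 2L + 1L
    for (s in seq_along(starts))
      gam[starts[s]:ends[s]] <- hh[phase[s], starts[s]:ends[s]]
  }
  gam
}

#' Simulate sequence-level genotypes and a half-sib pedigree
#'
#' Base allele frequencies follow a truncated arcsine (U-shaped)
#' distribution and seed one global founder-haplotype pool shared by every
#' country (a single breed). Country differentiation arises from
#' Dirichlet-perturbed haplotype sampling weights whose concentration is
#' set so that the expected FST equals the configured drift parameter;
#' because all countries draw from the same haplotypes, linkage phase and
#' genomic relationships are shared across countries, as within a breed.
#' Individuals are built as sire-gamete plus population-gamete mosaics
#' (about one crossover per chromosome), so linkage disequilibrium decays
#' with distance. The array panel is a random subset of common variants
#' (MAF >= 0.05), excluding designated causal variants unless
#' `qtl_on_array`; per-variant imputation-quality scores are drawn from a
#' mixture with roughly 60% above 0.4. The `hd` panel is a denser marker
#' chip containing every array marker plus a sample of lower-frequency
#' (MAF 0.01-0.05) markers; like the array it excludes causal variants
#' unless `qtl_on_array`, since marker chips tag causal alleles rather
#' than carry them.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix] with panel flags
#'   `panel_sequence`/`panel_array50k`/`panel_hd`, `is_qtl`, and
#'   imputation-quality columns `r2_ove`, `r2_aus`) and `pedigree`
#'   (animal_id, sire_id, dataset, birth_year).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_sequence_variants
  nc <- config$n_chrom
  ## genome layout
  per_chrom <- diff(round(seq(0, m, length.out = nc + 1)))
  chrom <- rep(seq_len(nc), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(config$chrom_length_bp, k))))
  chrom_ranges <- lapply(seq_len(nc), function(cc) range(which(chrom == cc)))
  ## base frequencies: arcsine, truncated at 0.01
  p0 <- stats::rbeta(m, 0.5, 0.5)
  p0 <- pmin(pmax(p0, 0.01), 0.99)
  ## one global founder-haplotype pool shared by every country (one breed);
  ## country drift = Dirichlet-perturbed haplotype sampling weights with
  ## concentration a = (1/FST - 1)/K, giving FST ~ 1/(a K + 1)
  K <- config$n_founder_hap
  ## two-tier ancestry: a small ancestral pool gives strong local LD, and
  ## founders recombine it into many genome-wide distinct haplotypes
  K0 <- config$n_ancestral_hap
  anc <- matrix(0L, K0, m)
  for (cc2 in seq_len(nc)) {
    rr <- chrom_ranges[[cc2]][1]:chrom_ranges[[cc2]][2]
    anc[, rr] <- .ancestral_chrom(K0, p0[rr])
  }
  pool <- t(vapply(seq_len(K), function(i)
    .mosaic_gamete(anc, chrom_ranges, config$founder_block_rate),
    integer(m)))
  ids <- character(0); sires <- character(0); countries <- character(0)
  dos <- matrix(0L, sum(config$animals_per_country), m)
  row <- 0L
  for (cc in seq_len(config$n_countries)) {
    fst <- config$country_fst[cc]
    w <- if (fst <= 1e-12) rep(1 / K, K) else {
      a <- (1 / fst - 1) / K
      g0 <- stats::rgamma(K, shape = a)
      g0 / sum(g0)
    }
    lab <- paste0("P", cc)
    nsire <- config$n_sires_per_country[cc]
    sire_gam <- lapply(seq_len(nsire), function(s)
      list(.mosaic_gamete(pool, chrom_ranges, config$crossover_rate, w),
           .mosaic_gamete(pool, chrom_ranges, config$crossover_rate, w)))
    na <- config$animals_per_country[cc]
    sire_of <- sample.int(nsire, na, replace = TRUE)
    unknown <- stats::runif(na) < config$prop_unknown_sire
    for (a in seq_len(na)) {
      row <- row + 1L
      pat <- if (unknown[a]) .mosaic_gamete(pool, chrom_ranges, config$crossover_rate, w)
             else .meiosis(sire_gam[[sire_of[a]]][[1]], sire_gam[[sire_of[a]]][[2]],
                           chrom_ranges, config$crossover_rate)
      mat <- .mosaic_gamete(pool, chrom_ranges, config$crossover_rate, w)
      dos[row, ] <- pat + mat
      ids <- c(ids, sprintf("%s_A%04d", lab, a))
      sires <- c(sires, if (unknown[a]) NA_character_
                 else sprintf("%s_S%02d", lab, sire_of[a]))
      countries <- c(countries, lab)
    }
  }
  maf <- compute_maf(dos)
  qtl_pool <- which(maf >= config$qtl_maf_min)
  if (length(qtl_pool) < config$n_qtl)
    stop("fewer than n_qtl variants pass the causal MAF floor")
  qtl <- sample(qtl_pool, config$n_qtl)
  is_qtl <- seq_len(m) %in% qtl
  common <- which(maf >= 0.05 & (config$qtl_on_array | !is_qtl))
  array_idx <- sort(sample(common, round(config$array_fraction * length(common))))
  ## hd chip: every array marker plus a sample of lower-MAF markers
  rare_pool <- setdiff(which(maf >= 0.01 & maf < 0.05 &
                               (config$qtl_on_array | !is_qtl)), array_idx)
  hd_idx <- sort(c(array_idx, sample(rare_pool, round(0.6 * length(rare_pool)))))
  ## imputation quality: ~60% clear 0.4 in the discovery set
  good <- stats::runif(m) < 0.6
  r2_ove <- ifelse(good, stats::runif(m, 0.4, 1), stats::runif(m, 0, 0.4))
  r2_aus <- pmin(pmax(r2_ove + stats::rnorm(m, 0, 0.1), 0), 1)
  variants <- data.frame(
    id = sprintf("v%06d", seq_len(m)), chrom = as.character(chrom), pos = pos,
    ref = "A", alt = "B", is_qtl = is_qtl,
    panel_sequence = TRUE,
    panel_array50k = seq_len(m) %in% array_idx,
    panel_hd = seq_len(m) %in% hd_idx,
    r2_ove = r2_ove, r2_aus = r2_aus,
    stringsAsFactors = FALSE)
  birth_year <- sample(2013:2016, length(ids), replace = TRUE)
  g <- genotype_matrix(dos, ids, variants)
  ped <- data.frame(animal_id = ids, sire_id = sires, dataset = countries,
                    birth_year = birth_year, stringsAsFactors = FALSE)
  list(genotypes = g, pedigree = ped)
}

#' Simulate correlated trait phenotypes and component records
#'
#' Causal effects for the T configured traits are drawn from a multivariate
#' normal with the configured genetic correlations; true breeding values are
#' scaled so that each trait has heritability `h2[t]` against a unit
#' phenotypic variance. Besides the direct per-animal phenotypes
#' (`y_trait*`), component records (milk, fat, protein, body weight, daily
#' body-weight change, DMI) are generated such that the trait-1 genetic
#' signal is injected at the DMI-residual level: re-deriving RFI from the
#' records by the regression recipe recovers the injected values.
#'
#' @param g [genotype_matrix] from [simulate_genotypes()].
#' @param pedigree its pedigree.
#' @param config the same [sim_config()].
#' @return list with `animals` (per-animal true breeding values `tbv_trait*`
#'   and phenotypes `y_trait*`, plus `rfi_true`) and `records` (per-record
#'   component phenotypes with DIM, parity, HYS, contemporary group, age).
#' @export
simulate_traits <- function(g, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 77003L)
  T_ <- length(config$h2)
  n <- nrow(g$dosages)
  qtl <- which(g$variants$is_qtl)
  if (!length(qtl)) stop("genotypes carry no causal candidates")
  L <- tryCatch(chol(config$rg), error = function(e)
    stop("genetic correlation matrix is singular or not PD: ", conditionMessage(e)))
  eff <- matrix(stats::rnorm(length(qtl) * T_), ncol = T_) %*% L
  ## sparse pleiotropy: a QTL either affects every trait block or is
  ## private to one block (traits within a block always share QTL)
  blocks <- config$trait_blocks
  if (length(unique(blocks)) > 1) {
    nq <- length(qtl)
    shared <- stats::runif(nq) < config$pleiotropy_frac
    own <- sample(unique(blocks), nq, replace = TRUE)
    for (t in seq_len(T_))
      eff[!shared & own != blocks[t], t] <- 0
  }
  Q <- impute_mean(g$dosages[, qtl, drop = FALSE])
  pq <- colMeans(Q) / 2
  ## effects on the standardized-genotype scale (the GBLUP assumption:
  ## rarer causal alleles have larger per-allele effects)
  Z <- sweep(Q, 2, 2 * pq)
  Z <- sweep(Z, 2, sqrt(pmax(2 * pq * (1 - pq), 1e-8)), `/`)
  tbv <- Z %*% eff
  for (t in seq_len(T_)) {
    s <- stats::sd(tbv[, t])
    tbv[, t] <- if (s > 0) tbv[, t] / s * sqrt(config$h2[t]) else tbv[, t]
  }
  y <- tbv + matrix(stats::rnorm(n * T_), n) %*% diag(sqrt(1 - config$h2), T_)
  animals <- data.frame(pedigree,
                        stringsAsFactors = FALSE)
  for (t in seq_len(T_)) {
    animals[[paste0("tbv_trait", t)]] <- tbv[, t]
    animals[[paste0("y_trait", t)]] <- y[, t]
  }
  animals$rfi_true <- tbv[, 1]
  ## component records; trait-1 signal enters through the DMI residual
  pe <- stats::rnorm(n, 0, sqrt(1 - config$h2[1]))   # permanent environment
  rfi_animal <- config$rfi_sd * (tbv[, 1] + pe)       # kg/day scale
  nrec <- sample(1:3, n, replace = TRUE)
  idx <- rep(seq_len(n), nrec)
  nr <- length(idx)
  dim_ <- sample(5:306, nr, replace = TRUE)
  parity <- sample(1:4, nr, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  season <- sample(c("autumn", "winter", "spring", "summer"), nr, replace = TRUE)
  herd <- "H1"
  year <- pedigree$birth_year[idx] + 2L
  milk_a <- stats::rnorm(n, 20, 3)
  milk <- pmax(milk_a[idx] + stats::rnorm(nr, 0, 1), 1)
  fat <- pmax(0.04 * milk + stats::rnorm(nr, 0, 0.05), 0.01)
  protein <- pmax(0.033 * milk + stats::rnorm(nr, 0, 0.04), 0.01)
  bw <- pmax(stats::rnorm(n, 600, 40)[idx] + stats::rnorm(nr, 0, 5), 300)
  dbw <- stats::rnorm(n, 0.1, 0.15)[idx]
  age <- pedigree$birth_year[idx] * 0 + 24 + 12 * (parity - 1) +
    sample(0:6, nr, replace = TRUE)
  ecm <- compute_ecm(milk, fat, protein)
  dmi <- 4 + 0.32 * ecm + 0.015 * bw + 1.5 * dbw - 0.003 * dim_ +
    0.2 * (parity > 1) + rfi_animal[idx] +
    stats::rnorm(nr, 0, config$rfi_record_noise)
  records <- data.frame(
    animal_id = pedigree$animal_id[idx], sire_id = pedigree$sire_id[idx],
    dataset = pedigree$dataset[idx], birth_year = pedigree$birth_year[idx],
    dim = dim_, parity = parity, herd = herd, year = year, season = season,
    hys = paste(herd, year, season, sep = ":"),
    cgroup = paste(pedigree$dataset[idx], year, season, sep = ":"),
    age = age, trial = "T1",
    milk = milk, fat = fat, protein = protein, ecm = ecm,
    bw = bw, mbw = bw, dbw = dbw, dmi = dmi,
    stringsAsFactors = FALSE)
  list(animals = animals, records = records, rfi_injected = rfi_animal)
}

#' Subset a genotype matrix to a panel
#'
#' @param g a [genotype_matrix] whose variant table has `panel_*` flags.
#' @param panel one of the panel labels (`"sequence"`, `"array50k"`, `"hd"`,
#'   or any label with a matching `panel_<label>` column).
#' @return a [genotype_matrix] restricted to the panel's variants.
#' @export
make_panel <- function(g, panel) {
  col <- paste0("panel_", panel)
  if (is.null(g$variants[[col]])) stop("unknown panel: ", panel)
  keep <- which(g$variants[[col]])
  if (!length(keep)) stop("panel '", panel, "' is empty")
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$animal_ids,
                  g$variants[keep, , drop = FALSE])
}

#' Simulate a complete analysis bundle
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_traits()] for one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `pedigree`, `animals`, `records`, `config`.
#' @export
simulate_bundle <- function(config) {
  sim <- simulate_genotypes(config)
  tr <- simulate_traits(sim$genotypes, sim$pedigree, config)
  list(genotypes = sim$genotypes, pedigree = sim$pedigree,
       animals = tr$animals, records = tr$records, config = config)
}
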