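## small in-code fixtures shared across test files

## unstructured HWE population: independent binomial dosages
hwe_genotypes <- function(n, m, maf_range = c(0.05, 0.95), seed = 1) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
  nchr <- min(5, m)
  vt <- data.frame(id = sprintf("v%05d", seq_len(m)),
                   chrom = as.character(rep_len(seq_len(nchr), m)),
                   pos = unlist(lapply(split(seq_len(m), rep_len(seq_len(nchr), m)),
                                       function(ii) sort(sample.int(1e7, length(ii))))),
                   stringsAsFactors = FALSE)
  vt <- vt[order(as.integer(vt$chrom), vt$pos), ]
  genotype_matrix(dos, sprintf("a%04d", seq_len(n)), vt)
}

## tiny structured bundle for pipeline-level tests
small_bundle <- function(seed = 1, ...) {
  simulate_bundle(sim_config(n_countries = 2,
                             animals_per_country = c(120, 120),
                             n_sires_per_country = 12,
                             n_sequence_variants = 1200,
                             n_qtl = 40, qtl_on_array = TRUE,
                             seed = seed, ...))
}

trait_records <- function(animals, column = "y_trait1", trait = "t1",
                          datasets = NULL) {
  df <- if (is.null(datasets)) animals
        else animals[animals$dataset %in% datasets, , drop = FALSE]
  data.frame(animal_id = df$animal_id, dataset = df$dataset,
             trait = trait, y = df[[column]], stringsAsFactors = FALSE)
}
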