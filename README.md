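# rfigp — genomic prediction of residual feed intake across populations

Feed efficiency is one of the most expensive traits to measure in dairy
cattle: residual feed intake (RFI) requires individual feed-intake
recording, so no single country accumulates enough phenotyped cows for
accurate genomic prediction. `rfigp` implements, as a tested R pipeline,
the two ways international partners can share information to lift the
accuracy of genomic breeding values (GEBV) for RFI in a focal population:

1. **sharing phenotypes** — multi-trait GBLUP in which RFI measured in
   each country is treated as a correlated trait (or merged into one
   standardised trait), and
2. **sharing GWAS summary statistics** — sequence variants selected from a
   multi-trait meta-analysis of independent overseas scans are combined
   with the standard 50k array in a variance-weighted genomic relationship
   matrix (GRM).

## The models

*Phenotype derivation.* RFI is the residual of dry matter intake:
`RFI = DMI − (mean + fixed effects + b1·ECM + b2·MBW + b3·ΔBW + …)`,
with `ECM = 0.1·milk + 5.2·fat + 2.6·protein` (kg/day) and ΔBW the
day-to-day difference of a fifth-order orthogonal-polynomial regression of
body weight on days in milk.

*GBLUP / GREML.* `y_T = X_T b_T + Z_T g_T + e_T`, `g ~ N(0, G ⊗ P)`,
`var(e) = R ⊗ I`, where `G` is the Yang-method GRM
(`G_jk = (1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i)/(2p_i(1−p_i))` off the
diagonal, with Yang's distinct diagonal estimator) and `P`, `R` are the
T×T genetic and residual (co)variance matrices, estimated by AI-REML with
EM fallback. Genomic heritability is `h² = P_tt/(P_tt+R_tt)`; genetic
correlation `r_g = P_12/√(P_11 P_22)`.

*GWAS and meta-analysis.* Each sequence variant is tested one at a time in
the mixed model (two-stage, null variance components fixed); the
multi-trait statistic is `χ²_i = t_i' V⁻¹ t_i` with `t_i` the signed
t-values and `V` their correlation matrix over all variants (df = number
of traits). Variants are filtered on imputation quality (R² > 0.4 in at
least one dataset) and MAF (> 0.006), and the top 3 variants with
P < 0.001 are taken per 100-kb window sliding by 50 kb.

*Evaluation.* Accuracy is `cor(GEBV, corrected phenotype)/√h²` averaged
over four validation folds (by birth-year cohort, or by dealing whole
paternal half-sib families to folds); its SE is the SD of the four fold
accuracies divided by 2; dispersion bias is the regression slope of
corrected phenotypes on GEBV (1 = unbiased).

A synthetic multi-country generator (`simulate_bundle()`) provides
Holstein-like data — one shared founder-haplotype pool with mild
country-level differentiation (FST ≈ 0.01–0.02), half-sib families,
heterozygosity ≈ 0.33, causal variants present at sequence density but
absent from the array — so the whole workflow is testable without any
proprietary data.

## Worked example

```r
library(rfigp)

bundle <- simulate_bundle(sim_config(seed = 5))

## derive RFI from component records and check the spread
rfi <- derive_rfi(bundle$records, rfi_spec_cow())
sd(rfi$rfi)
#> [1] 1.309982

## population structure on the dense panel
hd  <- make_panel(bundle$genotypes, "hd")
fst <- pairwise_fst(hd, bundle$pedigree$dataset)
round(range(fst$gst_prime[upper.tri(fst$gst_prime)]), 3)
#> [1] 0.014 0.018

## focal-country baseline vs adding overseas records as a correlated trait
trs <- list(list(name = "rfi",     datasets = "P1",            column = "y_trait1"),
            list(name = "rfi_ove", datasets = paste0("P", 2:7), column = "y_trait2"))
base <- run_scenario(scenario("base", traits = trs[1], design = "cohort"), bundle)
biv  <- run_scenario(scenario("biv",  traits = trs,    design = "cohort"), bundle)
report_difference(list(base = base, biv = biv), "base")
#>   scenario  accuracy difference
#> 1     base 0.4925444   0.000000
#> 2      biv 0.5775907   8.504639
```

The baseline scenario trains on the focal cohort only; the bivariate
scenario adds the overseas cohorts as a genetically correlated trait
(r_g ≈ 0.95) and the difference column reports the accuracy gain in
percentage points.

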