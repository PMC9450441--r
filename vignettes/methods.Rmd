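---
title: "Models and design choices in rfigp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in rfigp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rfigp` implements a complete genomic-prediction workflow for residual
feed intake (RFI) in dairy cattle whose phenotype data are scattered over
several countries. This vignette explains the statistical models, the
synthetic data the package tests itself against, and the design decisions
taken where more than one defensible choice existed. No empirical claim is
made here beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## Phenotype derivation

RFI is defined as the residual of dry matter intake (DMI, kg/day) after
regression on production, body size and body-weight change. Two model
variants are shipped:

* `rfi_spec_cow()` — mean + contemporary group + parity (factors), DIM,
  energy-corrected milk (ECM), mean body weight (MBW), daily body-weight
  change (ΔBW) as covariates;
* `rfi_spec_overseas()` — mean + parity-by-lactation-stage + herd-year-
  season + trial (factors), DIM, a quadratic orthogonal polynomial of age
  at calving, ECM, MBW, ΔBW.

ECM is `0.1·milk + 5.2·fat + 2.6·protein`, all in kg/day. ΔBW comes from a
fifth-order orthogonal-polynomial regression of body weight on days in
milk (restricted to DIM 5–306, at least 7 records spanning 30 days),
differenced between consecutive days. `derive_rfi()` fits ordinary least
squares, drops records with missing covariates, drops single-level
factors with a warning, and averages residuals per animal when an animal
has several lactation records. RFI is a residual, so the factor baseline
is immaterial; the test suite asserts invariance of RFI to affine
recoding of the covariates.

Choices worth naming:

* **Sample SD** (n−1) is used by `standardise()`; standardisation is
  applied within each country's dataset before pooling, so a pooled table
  has exactly zero mean and unit SD per country.
* Parity-by-stage uses parity {1, 2, 3+} crossed with lactation stages
  {≤30, 31–100, 101–200, >200} DIM; seasons are calendar quarters
  starting with autumn = October–December.
* The per-record DIM (not a per-lactation mean) enters as the DIM
  covariate, and the age polynomial is interpreted as degree 2.

## Genomic relationship matrices

`build_grm_yang()` uses the Yang-style estimator: off-diagonals
`(1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i)/(2p_i(1−p_i))` and the distinct
diagonal estimator `1 + (1/N) Σ_i (x_ij² − (1+2p_i)x_ij + 2p_i²)/(2p_i(1−p_i))`,
with allele frequencies taken from the analysed sample. Missing dosages
are mean-imputed per variant at GRM/GWAS time only; stored genotypes are
never modified. The MAF floor defaults to `clamp(10/n, 0.01, 0.05)`, which
guarantees at least 20 segregating copies of the minor allele.

A weighted GRM merges an array-marker GRM and a selected-sequence-variant
GRM as `(σ²_SNP·G_SNP + σ²_seq·G_seq)/(σ²_SNP + σ²_seq)`, the two genetic
variances being estimated by separate univariate GREML fits on the
training records.

Structure diagnostics: PCA of the (double-centered) GRM with scores
`eigenvector·√eigenvalue`; pairwise differentiation as multi-locus
`G_ST = Σ(H_T − H_S)/ΣH_T` plus Hedrick's standardised `G'_ST`
(ratio-of-sums across loci, not mean of ratios, for stable behaviour at
low-MAF variants — both are reported, the NJ tree uses `G'_ST`);
neighbour joining via `ape::nj` with negative branches clamped to zero
and the deficit moved to the sibling edge; and three heterozygosities per
group (observed `HE_o`, Hardy–Weinberg `HE_oHW`, and `HE_pr = HE_base(1−F)`
with `F` the group's mean GRM diagonal minus one). The inbreeding
definition behind `HE_pr` is GRM-based because a pedigree-based
alternative would need depth the data model does not carry.

## GREML and GBLUP

The multi-trait model is `y_T = X_T b_T + Z_T g_T + e_T` with
`g ~ N(0, G ⊗ P)` and `var(e) = R ⊗ I`; "traits" are typically the same
biological trait measured in different cohorts, so each animal carries at
most one record per trait, and the country of origin enters as a fixed
effect whenever a trait spans more than one dataset label.

Estimation is restricted maximum likelihood by average-information (AI)
updates, with step-halving, an EM-flavoured fallback step when the AI
direction fails, and projection of `P` and `R` onto the positive
semi-definite cone (eigenvalue floor 1e-8) after every step. The
univariate case runs in the eigenbasis of the GRM, making each iteration
O(n); multivariate fits work with the dense phenotypic covariance. During
step-halving only the likelihood is evaluated (one Cholesky); gradients
and the AI matrix are formed once per accepted step. Convergence requires
|ΔlogL| < 1e-8 and relative parameter change < 1e-6; a fit whose
likelihood changes by less than 1e-4 on three consecutive accepted steps
while a bent parameter keeps bouncing on the constraint boundary (e.g. an
estimated genetic correlation pinned at 1) is declared converged at the
boundary. Standard errors come from the inverse AI matrix; `heritability()`
and `genetic_correlation()` propagate them by first-order delta method.

Residual covariance between two traits is estimated only when at least 30
animals carry both traits; disjoint cohorts make it unidentifiable and it
is then fixed at zero. Starting values are half the phenotypic variance
to each component, with genetic covariances started at 0.3 of the
geometric-mean genetic variance. With an identity GRM the genetic and
residual components are not separable; the fit flags this
(`identifiable = FALSE`) and reproduces the closed-form OLS restricted
likelihood.

`predict_gebv()` solves the mixed model at given components and returns
GEBV for *every* animal in the GRM, so validation animals (whose records
are masked) are predicted purely through genomic relationships. On small
instances the masked predictions equal a directly-computed conditional
expectation to 1e-8, and with a `ZZ'/m` kernel GBLUP reproduces the ridge
SNP-BLUP dual exactly.

## GWAS and the multi-trait meta statistic

`fit_null_model()` estimates the null variance components once and caches
the GRM eigendecomposition; `mlm_scan()` then tests each variant by
generalised least squares with the null components held fixed (the
standard two-stage approximation — at these sample sizes the difference
from per-variant REML is negligible, and it makes a 20k-variant scan a
matrix multiplication). The Wald test uses a t reference with
`n − rank(X) − 1` degrees of freedom rather than a normal, because
discovery sets of a few thousand animals are the target regime. Variants
with no genotypic variance after whitening are skipped with a reason
code.

The meta statistic is `χ²_i = t_i' V⁻¹ t_i` with `V` the Pearson
correlation of the signed t-vectors estimated **over all scanned
variants** (not only significant ones). Nearly collinear t-vectors
(|r| ≥ 0.999) get a 1e-6 ridge with a warning, which degrades a
duplicated trait gracefully to its single-trait χ².

## Variant selection

`filter_variants()` removes a variant only when its imputation R² is
≤ 0.4 in *both* named datasets, and when its MAF is ≤ 0.006 — both
boundaries are removals, matching the stated inequalities.
`select_top_windows()` slides 100-kb windows by 50 kb from position 0 of
each chromosome (half-open intervals), takes up to 3 variants with
P < 0.001 per window by ascending p (ties broken by larger |t|, then
lower position — a deterministic completion of an underdetermined rule),
and deduplicates across overlapping windows. Sets from the single-trait
scans and the meta scan are unioned by `combine_sets()`, and
`exclude_panel()` drops variants already on the array before the weighted
GRM is built.

## Cross-validation and accuracy

Two fold designs: `cohort_folds()` groups by birth year, merging trailing
(most recent, smallest) years down to exactly four folds;
`sire_family_folds()` deals whole paternal half-sib families to four
folds (largest first onto the smallest fold), keeping unknown-sire
animals in every training set. Accuracy is
`cor(GEBV, corrected phenotype)/√h²`, the SE of the four fold accuracies
is `sd/2` and is flagged approximate (folds share training animals), and
bias is the slope of corrected phenotypes on GEBV.

Three choices deserve explanation:

* **Corrected phenotypes** subtract fixed effects estimated on the
  training fold only, so no validation information leaks into the
  correction.
* **The h² in the accuracy denominator** is the genomic heritability of
  the validation-population trait from the array GRM, estimated once on
  the full focal dataset. Re-estimating it per fold is attractive in
  principle, but at a few hundred records per fold the REML estimate
  occasionally collapses toward zero and the accuracy ratio explodes;
  a single shared denominator also cancels exactly out of every
  between-scenario comparison. A floor of 0.05 guards the division.
* **Variance components are estimated once per scenario** on the full
  training composition and treated as known across folds (per-fold GEBV
  always mask validation phenotypes). This mirrors common practice in
  cross-validation studies and avoids fold-level variance collapse; the
  `refit_vc` switch restores per-fold re-estimation.

## The synthetic generator

`simulate_genotypes()` builds a Holstein-like multi-country population:

* **One shared ancestry.** A small pool of ancestral haplotypes per
  chromosome receives its alleles on the clades of a random-join
  genealogy (each variant picks a clade whose size matches a target
  frequency drawn from an arcsine distribution truncated at 0.01), so
  nearby variants riding the same or nested clades are strongly
  correlated — mutation-on-genealogy linkage disequilibrium. A larger
  founder pool (default 600) recombines the ancestors into fine mosaics
  (default 150 ancestral crossovers per chromosome), giving many
  genome-wide independent segments and hence a realistic effective
  number of chromosome segments, while local LD inside a block stays
  strong enough for array markers to tag causal variants.
* **Countries drift, but share LD.** Every country samples the *same*
  founder pool with Dirichlet-perturbed weights whose concentration is
  `(1/FST − 1)/K`, so the expected differentiation equals the configured
  drift parameter (default 0.01) while linkage phase and genomic
  relationships remain shared across countries — the "single cloud, one
  breed" regime in which cross-country information sharing can work at
  all.
* **Families.** Sires are simulated individuals; offspring receive a
  recombined sire gamete and a fresh population gamete, giving paternal
  half-sib families; a configurable fraction of animals has an unknown
  sire. Birth years are uniform over 2013–2016.
* **Panels.** The sequence panel is everything; the 50k-like array is a
  random half of the common (MAF ≥ 0.05) variants excluding causal ones;
  the HD panel is the array plus a sample of lower-frequency markers —
  marker chips tag causal alleles, they do not carry them. Per-variant
  imputation-quality scores follow a mixture with about 60% above 0.4.
* **Traits.** Causal effects for the configured traits are multivariate
  normal on the standardized-genotype scale (rarer causal alleles have
  larger per-allele effects, the assumption the Yang GRM encodes), scaled
  to the target heritabilities against unit phenotypic variance. The
  default three traits play the roles of RFI in the focal country, RFI
  overseas (genetic correlation 0.95 with the focal expression) and DMI
  overseas (0.6 with overseas RFI). The trait-1 signal is additionally
  injected at the DMI-residual level of the component records (milk,
  fat, protein, body weight, DMI; SD 1.3 kg/day), so deriving RFI by the
  regression recipe is a genuine recovery problem rather than a
  decorative step.

Calibration choices were made once, against the regimes the study design
implies, and are not tuned per test: the founder/ancestor/block defaults
put the four-fold baseline accuracy of a 400–600-cow focal set near 0.3
(the accuracy regime of a small national RFI reference), realized
heterozygosity near 0.33, and pairwise FST near 0.01–0.02. What the
generator does *not* emulate: lactation-curve biology,
genotype-by-environment interaction, per-country marker chips, and real
imputation error (quality scores are labels, not error processes) — so
green tests show the pipeline's statistics behave as designed, not that
any particular field dataset would reach the same numbers.

## Problem sizes and determinism

The test suite and acceptance script use desk-scale versions of the study
design, chosen as the smallest sizes at which each property is
statistically decidable: heritability recovery at n = 1500 with 4000
markers over 10 trait draws on one simulated genome (conditional Monte
Carlo: the empirical spread of the estimates then measures the same
conditional sampling variance the curvature-based SE reports);
genetic-correlation recovery with disjoint 600 + 2000 cohorts (again one
genome, effects redrawn per seed); null calibration
of the meta statistic on 20 000 independent variants; information-sharing
replicates with a 600-record focal set plus 2000 overseas records; and a
default bundle of seven countries (400 + 6×150 animals, 12 000 sequence
variants). Every stochastic step is seeded; the same seed reproduces the
same bundle byte for byte.

## Known limitations

* The AI-REML SEs are curvature-based; at constraint boundaries
  (correlations pinned at ±1) they are approximate.
* The two-stage GWAS slightly underestimates per-variant variance when a
  single variant explains a large trait fraction — immaterial for the
  polygenic regime targeted here.
* `HE_pr`'s inbreeding is GRM-diagonal-based by construction; with very
  small groups it inherits the diagonal's sampling noise.
* Window selection is positional only; no LD-based clumping is offered.
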