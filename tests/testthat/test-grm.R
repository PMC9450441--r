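test_that("Yang GRM matches hand-evaluated formulas", {
  g <- genotype_matrix(matrix(c(0L, 2L), 2, 1),
                       c("a", "b"),
                       data.frame(id = "v1", chrom = "1", pos = 100))
  G <- build_grm_yang(g, maf_min = 0.01)
  expect_equal(G$matrix["a", "b"], -2)
  expect_equal(G$n_variants, 1)
  ## identical animals: off-diagonals equal diagonals
  set.seed(1)
  row <- sample(0:2, 50, replace = TRUE)
  gid <- genotype_matrix(matrix(rep(row, each = 4), 4), letters[1:4],
                         data.frame(id = sprintf("v%02d", 1:50), chrom = "1",
                                    pos = 1:50))
  Gid <- build_grm_yang(gid, maf_min = 0.1)
  expect_lt(max(abs(Gid$matrix - Gid$matrix[1, 1])), 1e-12)
  expect_error(build_grm_yang(genotype_matrix(matrix(2L, 3, 1), c("x", "y", "z"),
                                              data.frame(id = "v", chrom = "1",
                                                         pos = 1)),
                              maf_min = 0.01), "MAF")
})

test_that("Yang GRM is calibrated on an unstructured HWE population", {
  G <- build_grm_yang(hwe_genotypes(500, 5000, seed = 2), maf_min = 0.01)
  expect_gt(mean(diag(G$matrix)), 0.98)
  expect_lt(mean(diag(G$matrix)), 1.02)
  off <- G$matrix[upper.tri(G$matrix)]
  expect_lt(abs(mean(off)), 0.01)
})

test_that("GRM is invariant to animal and variant order", {
  g <- hwe_genotypes(40, 300, seed = 3)
  G <- build_grm_yang(g, maf_min = 0.01)
  pa <- sample(nrow(g$dosages)); pv <- sample(ncol(g$dosages))
  g2 <- genotype_matrix(g$dosages[pa, pv], g$animal_ids[pa],
                        g$variants[pv, ])
  G2 <- build_grm_yang(g2, maf_min = 0.01)
  expect_lt(max(abs(G2$matrix[g$animal_ids, g$animal_ids] - G$matrix)), 1e-12)
})

test_that("the MAF floor guarantees 20 segregating allele copies", {
  expect_equal(effective_maf_threshold(2000), 0.01)
  expect_equal(effective_maf_threshold(200), 0.05)
  expect_equal(effective_maf_threshold(500), 0.02)
  expect_error(effective_maf_threshold(5), "at least 10")
})

test_that("weighted GRM aggregation is the variance-weighted mean", {
  A <- new_grm(diag(2), c("a", "b"), 10)
  B <- new_grm(2 * diag(2), c("a", "b"), 5)
  expect_equal(combine_weighted_grm(A, B, 1, 0)$matrix, A$matrix)
  expect_equal(combine_weighted_grm(A, B, 1, 1)$matrix,
               (A$matrix + B$matrix) / 2)
  expect_equal(combine_weighted_grm(A, B, 3, 1)$matrix, 1.25 * diag(2),
               ignore_attr = TRUE)
  expect_error(combine_weighted_grm(A, B, 0, 0), "positive")
  C <- new_grm(diag(2), c("a", "c"), 10)
  expect_error(combine_weighted_grm(A, C, 1, 1), "different animals")
})

test_that("GRM principal components recover block structure", {
  I4 <- new_grm(diag(4), letters[1:4], 1)
  p <- grm_pca(I4, 2, center = FALSE)
  expect_equal(p$eigenvalues, c(1, 1))
  blk <- new_grm(kronecker(diag(2), matrix(1, 3, 3)), letters[1:6], 1)
  pb <- grm_pca(blk, 1)
  s <- sign(pb$scores[, 1])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == -s[1]))
  expect_error(grm_pca(I4, 9), "exceeds")
  ## two drifted countries separate on PC1
  cfg <- sim_config(n_countries = 2, animals_per_country = 80,
                    n_sequence_variants = 2000, n_qtl = 20,
                    country_fst = c(0.03, 0.03), seed = 5)
  sim <- simulate_genotypes(cfg)
  G <- build_grm_yang(sim$genotypes, maf_min = "auto")
  pc <- grm_pca(G, 2)
  grps <- split(pc$scores[, 1], sim$pedigree$dataset)
  pooled_sd <- sqrt(mean(sapply(grps, var)))
  expect_gt(abs(mean(grps[[1]]) - mean(grps[[2]])), 3 * pooled_sd)
})

test_that("pairwise differentiation matches hand-worked Hedrick values", {
  ## equal frequencies -> zero
  dos <- rbind(matrix(c(2, 2, 1, 0, 0), 5, 2), matrix(c(2, 2, 1, 0, 0), 5, 2))
  g <- genotype_matrix(dos, sprintf("a%d", 1:10),
                       data.frame(id = c("v1", "v2"), chrom = "1",
                                  pos = c(1, 2)))
  f <- pairwise_fst(g, rep(c("A", "B"), each = 5))
  expect_equal(f$gst[1, 2], 0)
  ## fixation -> 1 for both measures
  gfix <- genotype_matrix(rbind(matrix(2, 3, 1), matrix(0, 3, 1)),
                          sprintf("b%d", 1:6),
                          data.frame(id = "v1", chrom = "1", pos = 1))
  ffix <- pairwise_fst(gfix, rep(c("A", "B"), each = 3))
  expect_equal(ffix$gst[1, 2], 1)
  expect_equal(ffix$gst_prime[1, 2], 1)
  ## p1 = 0.6, p2 = 0.4: G_ST = 0.04, G'_ST = 0.04 * 1.48 / 0.52
  d1 <- c(2, 2, 2, 1, 1, 1, 1, 1, 1, 0)   # 12/20 = 0.6
  d2 <- c(2, 1, 1, 1, 1, 1, 1, 0, 0, 0)   # 8/20 = 0.4
  gh <- genotype_matrix(cbind(c(d1, d2)), sprintf("c%02d", 1:20),
                        data.frame(id = "v1", chrom = "1", pos = 1))
  fh <- pairwise_fst(gh, rep(c("A", "B"), each = 10))
  expect_equal(fh$gst[1, 2], 0.04, tolerance = 1e-12)
  expect_equal(fh$gst_prime[1, 2], 0.04 * (1 + 0.48) / 0.52, tolerance = 1e-12)
  ## monomorphic everywhere is undefined
  gm <- genotype_matrix(matrix(2L, 4, 1), sprintf("d%d", 1:4),
                        data.frame(id = "v1", chrom = "1", pos = 1))
  expect_error(pairwise_fst(gm, rep(c("A", "B"), each = 2)), "monomorphic")
})

test_that("label permutation collapses FST toward zero", {
  cfg <- sim_config(n_countries = 2, animals_per_country = 100,
                    n_sequence_variants = 2000, n_qtl = 20,
                    country_fst = c(0.03, 0.03), seed = 6)
  sim <- simulate_genotypes(cfg)
  f <- pairwise_fst(sim$genotypes, sim$pedigree$dataset)
  set.seed(1)
  fperm <- pairwise_fst(sim$genotypes, sample(sim$pedigree$dataset))
  expect_lt(fperm$gst[1, 2], f$gst[1, 2] / 5)
})

test_that("neighbour joining recovers an additive tree exactly", {
  ## tree ((A:1,B:2):1.5,(C:3,D:4)); additive path distances
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5.5; D["A", "D"] <- 6.5
  D["B", "C"] <- 6.5; D["B", "D"] <- 7.5; D["C", "D"] <- 7
  D <- D + t(D)
  nwk <- nj_tree(D)
  tr <- ape::read.tree(text = nwk)
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_lt(max(abs(cd - D)), 1e-10)
  ## n = 3 is fully determined
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- ape::read.tree(text = nj_tree(D3))
  c3 <- ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)]
  expect_lt(max(abs(c3 - D3)), 1e-10)
  ## permuting label order leaves the topology invariant
  perm <- c(3, 1, 4, 2)
  t2 <- ape::read.tree(text = nj_tree(D[perm, perm]))
  c2 <- ape::cophenetic.phylo(t2)[rownames(D), colnames(D)]
  expect_lt(max(abs(c2 - D)), 1e-10)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("heterozygosity measures agree under Hardy-Weinberg", {
  g <- hwe_genotypes(500, 5000, seed = 7)
  G <- build_grm_yang(g, maf_min = 0.01)
  grp <- rep(c("A", "B"), length.out = 500)
  rep_ <- heterozygosity_report(g, G, grp)
  expect_lt(max(abs(rep_$he_o - rep_$he_ohw)), 0.01)
  expect_lt(max(abs(rep_$he_o - rep_$he_pr)), 0.01)
  ## all-homozygous group
  dos <- rbind(matrix(2L, 3, 4), matrix(1L, 3, 4))
  gh <- genotype_matrix(dos, sprintf("h%d", 1:6),
                        data.frame(id = sprintf("v%d", 1:4), chrom = "1",
                                   pos = 1:4))
  Gh <- new_grm(diag(6), gh$animal_ids, 4)
  rh <- heterozygosity_report(gh, Gh, rep(c("hom", "het"), each = 3))
  expect_equal(rh$he_o[rh$group == "hom"], 0)
})
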