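test_that("heterozygosity matches the hand-computed single-site example", {
  # one site, genotypes {AA, Aa, aa}: H_o = 1/3; p = 0.5,
  # unbiased H_e = 0.5 * 2n/(2n-1) = 0.5 * 6/5 = 0.6
  g <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1), rep("a", 3))
  hs <- het_stats(g)
  expect_equal(hs$ho[hs$population == "a"], 1 / 3)
  expect_equal(hs$he[hs$population == "a"], 0.6)
})

test_that("all-heterozygote sites give H_o = 1 and monomorphic sites drop", {
  calls <- cbind(rep(1L, 4), rep(2L, 4))  # het site + monomorphic site
  g <- toy_geno(calls, rep("a", 4))
  hs <- het_stats(g)
  expect_equal(hs$ho[1], 1)               # the monomorphic site is excluded
})

test_that("F_IS is 1 for all-homozygote 50/50 sites and HWE sims center at 0", {
  g <- toy_geno(matrix(c(rep(0L, 5), rep(2L, 5)), ncol = 1), rep("a", 10))
  set.seed(15)
  f <- fis_permutation(g, n_perm = 99)
  expect_equal(f$fis, 1)
  expect_lt(f$p_value, 0.1)
  # HWE-simulated population: F_IS small, permutation null centered at 0
  set.seed(16)
  calls <- sapply(runif(150, 0.2, 0.8), function(p) rbinom(40, 2, p))
  fh <- fis_permutation(toy_geno(calls, rep("a", 40)), n_perm = 199)
  expect_lt(abs(fh$fis), 0.1)
  expect_gt(fh$p_value, 0.05)
})

test_that("F_IS permutation test holds its nominal type-I error rate", {
  set.seed(17)
  n_rep <- 120
  ps <- vapply(seq_len(n_rep), function(b) {
    calls <- sapply(runif(60, 0.2, 0.8), function(p) rbinom(25, 2, p))
    fis_permutation(toy_geno(calls, rep("a", 25)), n_perm = 99)$p_value
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  expect_lt(abs(rej - 0.05), 2 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("nucleotide diversity follows the normalized unbiased estimator", {
  # 1 variant at p = 0.5 among 100 callable sites, large n: pi ~ 0.005
  g <- toy_geno(matrix(rep(c(0L, 2L), 50), ncol = 1), rep("a", 100))
  pi1 <- nucleotide_diversity(g, total_sites = list(all = 100))
  expect_equal(unname(pi1["pi_all"]),
               2 * 0.5 * 0.5 * 200 / 199 / 100, tolerance = 1e-12)
  expect_equal(unname(pi1["pi_all"]), 0.005, tolerance = 0.01)
  # doubling the callable total halves pi
  pi2 <- nucleotide_diversity(g, total_sites = list(all = 200))
  expect_equal(unname(pi2["pi_all"]), unname(pi1["pi_all"]) / 2)
  # no variants -> 0; missing class totals -> error
  g0 <- toy_geno(matrix(0L, 5, 3), rep("a", 5))
  expect_equal(unname(
    nucleotide_diversity(g0, total_sites = list(all = 50))["pi_all"]), 0)
  expect_error(nucleotide_diversity(g, site_classes = rep("other", 1),
                                    total_sites = list(all = 10)),
               "zero_fold")
  # class split
  g2 <- toy_geno(cbind(rep(c(0L, 2L), 5), rep(c(0L, 1L), 5)), rep("a", 10))
  pis <- nucleotide_diversity(g2, c("zero_fold", "four_fold"),
                              list(all = 100, zero_fold = 40,
                                   four_fold = 20))
  expect_gt(pis["pi_4"], pis["pi_0"] * 0)  # both defined
  expect_equal(unname(pis["pi_0"]),
               2 * 0.5 * 0.5 * 20 / 19 / 40, tolerance = 1e-12)
})

test_that("pi and per-site unbiased H_e agree on the same variant set", {
  cfg <- sim_config(n_pops = 3, n_per_pop = 15, n_snps = 60,
                    target_fst = 0.01, n_outlier_loci = 0, seed = 18)
  g <- simulate_genotypes(cfg)$genotypes
  pi_all <- nucleotide_diversity(g, total_sites = list(all = 1000))
  nobs <- colSums(!is.na(g$calls))
  p <- colSums(g$calls) / (2 * nobs)
  he <- 2 * p * (1 - p) * 2 * nobs / (2 * nobs - 1)
  expect_equal(unname(pi_all["pi_all"]) * 1000, sum(he), tolerance = 1e-10)
})

test_that("WC F_ST equals the independent scalar oracle on toy tables", {
  # textbook two-population, one-locus table: n1 = n2 = 10, p = 0.2 / 0.8,
  # HWE-proportioned genotype counts
  pop1 <- c(rep(0L, 7), 2L, 1L, 1L)          # p = 0.2, 2 hets
  pop2 <- c(rep(2L, 7), 0L, 1L, 1L)          # p = 0.8
  g <- toy_geno(matrix(c(pop1, pop2), ncol = 1), rep(c("a", "b"), each = 10))
  f <- wc_fst(g, pairwise = TRUE)
  oracle <- wc_abc_oracle(list(pop1, pop2))
  expect_equal(f$per_locus$a, oracle[1], tolerance = 1e-12)
  expect_equal(f$per_locus$b, oracle[2], tolerance = 1e-12)
  expect_equal(f$per_locus$c, oracle[3], tolerance = 1e-12)
  expect_equal(f$global, oracle[1] / sum(oracle), tolerance = 1e-12)
  expect_equal(f$pairwise["a", "b"], f$global, tolerance = 1e-12)

  # multi-locus with missing data and unequal sizes
  set.seed(19)
  calls <- sapply(runif(40, 0.1, 0.9), function(p) rbinom(27, 2, p))
  calls[sample(length(calls), 60)] <- NA
  g2 <- toy_geno(calls, rep(c("a", "b", "c"), c(12, 8, 7)))
  f2 <- wc_fst(g2, pairwise = FALSE)
  expect_equal(f2$global, wc_fst_oracle(g2), tolerance = 1e-12)
})

test_that("identical populations give non-positive F_ST with p ~ 1", {
  set.seed(20)
  block <- sapply(runif(80, 0.2, 0.8), function(p) rbinom(12, 2, p))
  g <- toy_geno(rbind(block, block), rep(c("a", "b"), each = 12))
  f <- wc_fst(g, pairwise = TRUE, n_perm = 99)
  expect_lte(f$global, 0)
  expect_gt(f$pairwise_p["a", "b"], 0.5)
})

test_that("global F_ST is invariant to site and sample order", {
  cfg <- sim_config(n_pops = 5, n_per_pop = 10, n_snps = 120,
                    target_fst = 0.05, n_outlier_loci = 0, seed = 21)
  g <- simulate_genotypes(cfg)$genotypes
  f0 <- wc_fst(g, pairwise = FALSE)$global
  set.seed(22)
  gs <- subset_geno_for_test(g, sample(nrow(g$calls)), sample(ncol(g$calls)))
  expect_equal(wc_fst(gs, pairwise = FALSE)$global, f0, tolerance = 1e-12)
})

test_that("IBD regression recovers exact linear structure and detects IBD", {
  k <- 10
  d <- as.matrix(dist(cbind(seq_len(k), 0)))
  fst <- 0.001 + 0.002 * d
  diag(fst) <- 0
  set.seed(23)
  r <- suppressWarnings(ibd_regression(fst, d, n_perm = 199))
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.002, tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
  expect_error(ibd_regression(fst, matrix(1, k, k), n_perm = 9), "constant")
  # structureless matrices: p roughly uniform
  set.seed(24)
  ps <- vapply(1:40, function(b) {
    f2 <- matrix(0, k, k)
    f2[lower.tri(f2)] <- rnorm(k * (k - 1) / 2)
    f2 <- f2 + t(f2)
    ibd_regression(f2, d, n_perm = 99)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("genotype PCA separates diverged populations, not panmixia", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 30, n_snps = 500,
                    target_fst = 0.2, n_outlier_loci = 0, seed = 25)
  g <- simulate_genotypes(cfg)$genotypes
  pc <- genotype_pca(g, n_axes = 4)
  grp <- g$samples$population
  sep <- abs(mean(pc$scores[grp == "pop1", 1]) -
               mean(pc$scores[grp == "pop2", 1]))
  expect_gt(sep, 2 * (sd(pc$scores[grp == "pop1", 1]) +
                        sd(pc$scores[grp == "pop2", 1])) / 2)
  expect_gt(pc$var_frac[1] / pc$var_frac[2], 3)
  # duplicated individuals get identical scores
  g2 <- subset_geno_for_test(g, c(1, 1, 2:10), seq_len(500))
  pc2 <- genotype_pca(g2, n_axes = 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-9)
})
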