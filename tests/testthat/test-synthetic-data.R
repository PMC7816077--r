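test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_pops = 0), "population")
  expect_error(sim_config(target_fst = 1), "target_fst")
  expect_error(sim_config(n_outlier_loci = 50, n_snps = 10), "exceeds")
  expect_error(sim_config(h2_marker = 1), "h2_marker")
  expect_error(sim_config(outlier_pops = 1:30, n_pops = 5), "existing")
})

test_that("F = 0 collapses all populations onto the ancestral frequency", {
  cfg <- sim_config(n_pops = 5, n_per_pop = 4, n_snps = 50, target_fst = 0,
                    n_outlier_loci = 0, seed = 1)
  sim <- simulate_genotypes(cfg)
  expect_equal(sim$truth$pop_freqs,
               matrix(rep(sim$truth$ancestral_freqs, each = 5), nrow = 5))
})

test_that("realized multi-locus WC F_ST tracks the Balding-Nichols target", {
  ests <- vapply(1:3, function(s) {
    cfg <- sim_config(n_pops = 15, n_per_pop = 25, n_snps = 3000,
                      target_fst = 0.1, n_outlier_loci = 0, seed = s)
    wc_fst(simulate_genotypes(cfg)$genotypes, pairwise = FALSE)$global
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.1), 0.01)
})

test_that("a full shift with a rare ancestral allele fixes outlier pops", {
  cfg <- sim_config(n_pops = 6, n_per_pop = 10, n_snps = 200,
                    target_fst = 0.004, n_outlier_loci = 5,
                    outlier_pops = 1:2, outlier_freq_shift = 1.0, seed = 3)
  sim <- simulate_genotypes(cfg)
  out <- sim$truth$outlier_ids
  expect_true(all(sim$truth$pop_freqs[1:2, out] == 1))
  # other populations keep the rare ancestral frequency
  expect_true(all(sim$truth$pop_freqs[3:6, out] < 0.15))
  # genotypes in outlier populations are fixed for the alt allele
  expect_true(all(sim$genotypes$calls[1:20, out] == 2L))
})

test_that("within-population genotype frequencies are consistent with HWE", {
  cfg <- sim_config(n_pops = 8, n_per_pop = 50, n_snps = 400,
                    target_fst = 0.02, n_outlier_loci = 0, seed = 5)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes
  set.seed(1)
  pops <- split(seq_len(nrow(g$calls)), g$samples$population)
  ps <- unlist(lapply(pops[1:4], function(idx) {
    calls <- g$calls[idx, ]
    vapply(seq_len(ncol(calls)), function(l) {
      x <- calls[, l]
      na <- sum(x)
      if (na == 0 || na == 2 * length(x)) return(NA_real_)
      hwe_exact_p(sum(x == 1), length(x), na)
    }, numeric(1))
  }))
  ps <- ps[!is.na(ps)]
  rej <- mean(ps <= 0.05)
  # the exact test is conservative under discreteness: at or below nominal
  expect_lte(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / length(ps)))
  expect_gt(rej, 0.005)
})

test_that("noise-free environments are exact linear functions of geography", {
  cfg <- sim_config(n_pops = 10, n_env_vars = 12, env_noise_sd = 0, seed = 2)
  env <- simulate_environment(cfg)
  centered <- scale(env$env, scale = FALSE)
  expect_lte(qr(centered)$rank, 2)
})

test_that("the GDD5-like variable is strongly rank-correlated with latitude", {
  env <- simulate_environment(sim_config(seed = 4))
  rho <- cor(env$env[, "GDD5"], env$coords$latitude, method = "spearman")
  expect_gt(abs(rho), 0.9)
  expect_lt(rho, 0)  # fewer degree days further north
})

test_that("low-noise 68-variable environments concentrate on few PC axes", {
  cfg <- sim_config(n_env_vars = 68, env_noise_sd = 0.05, seed = 6)
  env <- simulate_environment(cfg)
  pc <- prcomp(env$env, center = TRUE, scale. = TRUE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_gte(ve[3], 0.95)
})

test_that("stored truth satisfies the Q_ST identity and the latent targets", {
  cfg <- sim_config(n_pops = 12, n_per_pop = 40, n_snps = 500,
                    n_causal = 40, qst_target = 0.8, n_outlier_loci = 0,
                    seed = 7)
  sim <- simulate_genotypes(cfg)
  d <- simulate_damage(cfg, sim$genotypes, sim$truth)
  tr <- d$truth
  expect_identical(tr$true_qst,
                   tr$true_sigmaB2 / (tr$true_sigmaB2 + 2 * tr$true_sigmaW2))
  # realized between/within variance of the stored latent components
  shift_var <- var(tr$pop_shift)
  expect_lt(abs(shift_var / (shift_var + 2 * tr$true_sigmaW2) - 0.8), 0.05)
  expect_equal(tr$true_h2, cfg$h2_marker, tolerance = 1e-12)
})

test_that("zero causal loci and zero adaptive shift remove population signal", {
  cfg <- sim_config(n_pops = 8, n_per_pop = 60, n_snps = 200, n_causal = 0,
                    qst_target = 0, n_outlier_loci = 0, seed = 8)
  sim <- simulate_genotypes(cfg)
  d <- simulate_damage(cfg, sim$genotypes, sim$truth)
  expect_true(all(d$truth$pop_shift == 0))
  fit <- kruskal.test(d$damage$score, factor(d$damage$population))
  expect_gt(fit$p.value, 0.01)
})

test_that("edge seedlings are damaged more on average", {
  cfg <- sim_config(n_pops = 5, n_per_pop = 2000, n_snps = 20, n_causal = 0,
                    qst_target = 0, n_outlier_loci = 0, edge_effect = 0.3,
                    seed = 9)
  sim <- simulate_genotypes(cfg)
  d <- simulate_damage(cfg, sim$genotypes, sim$truth)$damage
  expect_gt(mean(d$score[d$kantf == 1]), mean(d$score[d$kantf == 0]))
})

test_that("a dataset round-trips through the plain-text writers", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 6, n_snps = 40,
                    n_causal = 5, n_outlier_loci = 2, seed = 10)
  gsim <- simulate_genotypes(cfg)
  env <- simulate_environment(cfg)
  dmg <- simulate_damage(cfg, gsim$genotypes, gsim$truth)
  dir <- tempfile()
  write_dataset(list(genotypes = gsim$genotypes, env = env$env,
                     coords = env$coords, damage = dmg$damage,
                     truth = dmg$truth), dir)
  expect_true(all(file.exists(file.path(
    dir, c("genotypes.vcf", "samples.tsv", "environment.tsv",
           "coords.tsv", "damage.tsv", "truth.json")))))
  g2 <- read_vcf(file.path(dir, "genotypes.vcf"),
                 pop_map = gsim$genotypes$samples)
  expect_identical(unname(g2$calls), unname(gsim$genotypes$calls))
})
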