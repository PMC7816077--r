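# The hierarchical Poisson damage model and its posterior summaries.

make_damage <- function(npop = 12, nper = 60, s2b = 0.3, s2w = 0.16,
                        s2r = 0.04, beta0 = log(1.2), bddi = -0.5,
                        seed = 1, cap = TRUE) {
  set.seed(seed)
  n <- npop * nper
  pop <- rep(sprintf("p%02d", seq_len(npop)), each = nper)
  u <- rnorm(npop, 0, sqrt(s2b)); names(u) <- unique(pop)
  repl <- sample(rep_len(1:2, n))
  pr <- paste(pop, repl)
  v <- rnorm(length(unique(pr)), 0, sqrt(s2r)); names(v) <- unique(pr)
  ddi <- sample(rep_len(seq(7, 34, 3), n))
  kant <- rbinom(n, 1, 0.3)
  eta <- beta0 + bddi * as.numeric(scale(ddi)) + 0.1 * kant +
    u[pop] + v[pr] + rnorm(n, 0, sqrt(s2w))
  score <- rpois(n, exp(eta))
  if (cap) score <- pmin(score, 6L)
  list(damage = data.frame(population = pop, rep = paste0("rep", repl),
                           ddi = ddi, kantf = kant,
                           score = as.integer(score),
                           stringsAsFactors = FALSE),
       u = u, s2b = s2b, s2w = s2w)
}

test_that("covariate standardization is idempotent and back-converts", {
  tab <- data.frame(ddi = c(7, 10, 13), latitude = c(60, 62.5, 65),
                    longitude = c(10, 20, 30))
  s1 <- standardize_covariates(tab)
  expect_equal(mean(s1$ddi), 0)
  expect_equal(sd(s1$latitude), 1)
  s2 <- standardize_covariates(s1)
  expect_equal(s2$ddi, s1$ddi)
  expect_identical(nrow(attr(s2, "scaling")), 3L)
  # a standardized-latitude effect of -0.55 with SD(lat) = 2.5 degrees
  # is -0.22 damage per degree north
  expect_equal(effect_per_unit(-0.55, attr(s1, "scaling"), "latitude"),
               -0.22, tolerance = 1e-12)
  expect_error(standardize_covariates(data.frame(ddi = c(1, 1))), "zero SD")
})

test_that("the Q_ST formula, its inverse and limits are exact", {
  expect_equal(qst_point(1, 1), 1 / 3)
  expect_equal(qst_point(0, 1), 0)
  expect_equal(qst_point(1, 0), 1)
  expect_error(qst_point(0, 0), "undefined")
  expect_error(qst_point(1, 1, h2 = 0), "h2")
  # inversion identity over a grid, including at reduced heritability
  for (q in c(0.1, 0.5, 0.82, 0.95)) {
    ratio <- qst_invert(q)
    expect_equal(qst_point(ratio, 1), q, tolerance = 1e-12)
    expect_equal(qst_invert(qst_point(ratio, 1, h2 = 0.56), h2 = 0.56),
                 ratio, tolerance = 1e-12)
  }
  # Q_ST is monotone decreasing in h2 at fixed variances
  qs <- sapply(seq(0.2, 1, 0.2), function(h) qst_point(2, 1, h2 = h))
  expect_true(all(diff(qs) < 0))
})

test_that("the published global estimate re-evaluates to 0.9 at h2 = 0.56", {
  ratio <- qst_invert(0.82, h2 = 1)
  expect_equal(ratio, 9.111, tolerance = 1e-3)
  q56 <- qst_point(ratio, 1, h2 = 0.56)
  expect_equal(round(q56, 1), 0.9)
})

test_that("score validation and degenerate inputs error cleanly", {
  d <- make_damage(npop = 3, nper = 10)$damage
  d2 <- d; d2$score[1] <- 9L
  expect_error(fit_damage_model(d2, iters = 50, burnin = 10), "0..6")
  d3 <- d[d$population == d$population[1], ]
  expect_error(fit_damage_model(d3, iters = 50, burnin = 10),
               "two populations")
  expect_error(fit_damage_model(d, geography = "fixed", iters = 50,
                                burnin = 10), "coords")
})

test_that("no between-population signal concentrates Q_ST near zero", {
  sim <- make_damage(npop = 10, nper = 50, s2b = 0, seed = 2)
  post <- suppressWarnings(fit_damage_model(sim$damage, iters = 1500,
                                            burnin = 700, thin = 2,
                                            seed = 3))
  expect_lt(post$qst_hpdi[1], 0.05)
  expect_lt(post$qst_estimate, 0.25)
})

test_that("the sampler recovers variance components checked against glmer", {
  skip_if_not_installed("lme4")
  sim <- make_damage(npop = 15, nper = 80, s2b = 0.3, s2w = 0.16, seed = 4,
                     beta0 = log(0.8), cap = TRUE)
  d <- sim$damage
  post <- suppressWarnings(fit_damage_model(d, iters = 3000, burnin = 1500,
                                            seed = 5))
  d$obs <- seq_len(nrow(d))
  d$z_ddi <- as.numeric(scale(d$ddi))
  gl <- lme4::glmer(
    score ~ z_ddi + kantf + (1 | population) + (1 | population:rep) +
      (1 | obs),
    data = d, family = stats::poisson())
  vc <- as.data.frame(lme4::VarCorr(gl))
  s2b_glmer <- vc$vcov[vc$grp == "population"]
  s2w_glmer <- vc$vcov[vc$grp == "obs"]
  # same data, same model family: point estimates agree to MC/REML slack
  expect_lt(abs(mean(post$sigmaB2) - s2b_glmer), 0.15)
  expect_lt(abs(mean(post$sigmaW2) - s2w_glmer), 0.1)
  # and the posterior covers the simulation truth
  expect_gt(sim$s2b, hpdi(post$sigmaB2, 0.99)[1])
  expect_lt(sim$s2b, hpdi(post$sigmaB2, 0.99)[2])
})

test_that("geographic fixed effects are recovered from a simulated cline", {
  set.seed(6)
  npop <- 16; nper <- 60; n <- npop * nper
  coords <- data.frame(population = sprintf("p%02d", 1:npop),
                       latitude = seq(58, 69, length.out = npop),
                       longitude = runif(npop, 5, 50))
  pop <- rep(coords$population, each = nper)
  zl <- as.numeric(scale(coords$latitude)); names(zl) <- coords$population
  zg <- as.numeric(scale(coords$longitude)); names(zg) <- coords$population
  ddi <- sample(rep_len(seq(7, 34, 3), n))
  zd <- as.numeric(scale(ddi))
  kant <- rbinom(n, 1, 0.3)
  repl <- sample(rep_len(1:2, n))
  truth <- c(bddi = -0.54, blat = -0.55, blong = -0.18)
  eta <- log(1.2) + truth["bddi"] * zd + truth["blat"] * zl[pop] +
    truth["blong"] * zg[pop] + 0.1 * kant + rnorm(n, 0, 0.4)
  dmg <- data.frame(population = pop, rep = paste0("rep", repl), ddi = ddi,
                    kantf = kant, score = pmin(rpois(n, exp(eta)), 6L))
  post <- suppressWarnings(fit_damage_model(
    dmg, coords = coords, geography = "fixed", iters = 3000,
    burnin = 1500, seed = 7))
  for (pair in list(c("s_ddi", "bddi"), c("s_lat", "blat"),
                    c("s_long", "blong"))) {
    dr <- post$beta[, pair[1]]
    ci <- hpdi(dr)
    expect_gt(truth[pair[2]], ci[1])
    expect_lt(truth[pair[2]], ci[2])
  }
})

test_that("LS-means are flat without signal and monotone under a cline", {
  sim <- make_damage(npop = 8, nper = 40, s2b = 0, seed = 8)
  post <- suppressWarnings(fit_damage_model(sim$damage, iters = 1200,
                                            burnin = 600, seed = 9))
  lsm <- ls_means(post)
  expect_lt(diff(range(lsm)) / mean(lsm), 0.6)
  # link scale drops the lognormal correction
  expect_true(all(ls_means(post, scale = "link") < log(ls_means(post))))

  cfg <- sim_config(n_pops = 12, n_per_pop = 60, n_snps = 300,
                    n_causal = 30, qst_target = 0.8, n_outlier_loci = 0,
                    seed = 10)
  gsim <- simulate_genotypes(cfg)
  d <- simulate_damage(cfg, gsim$genotypes, gsim$truth)
  post2 <- suppressWarnings(fit_damage_model(d$damage, iters = 2000,
                                             burnin = 1000, seed = 11))
  lsm2 <- ls_means(post2)
  lat <- d$truth$coords$latitude[match(names(lsm2),
                                       d$truth$coords$population)]
  expect_lt(cor(lsm2, lat, method = "spearman"), -0.9)
})

test_that("pairwise Q_ST has zero diagonal and tracks latitude separation", {
  cfg <- sim_config(n_pops = 10, n_per_pop = 60, n_snps = 300,
                    n_causal = 30, qst_target = 0.7, n_outlier_loci = 0,
                    seed = 12)
  gsim <- simulate_genotypes(cfg)
  d <- simulate_damage(cfg, gsim$genotypes, gsim$truth)
  post <- suppressWarnings(fit_damage_model(d$damage, iters = 2000,
                                            burnin = 1000, seed = 13))
  pq <- pairwise_qst(post)
  expect_true(all(diag(pq) == 0))
  expect_equal(pq, t(pq))
  lat <- d$truth$coords$latitude[match(colnames(pq),
                                       d$truth$coords$population)]
  dlat <- abs(outer(lat, lat, "-"))
  lw <- lower.tri(pq)
  expect_gt(cor(pq[lw], dlat[lw], method = "spearman"), 0.6)
})
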