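# PCNM predictors, forward selection, RDA and the outlier scan.

sim_freqs <- function(k = 24, p = 300, seed = 1) {
  set.seed(seed)
  scale(matrix(rnorm(k * p, 0, 0.05), k, p,
               dimnames = list(paste0("pop", 1:k), paste0("s", 1:p))),
        scale = FALSE)
}

test_that("PCNM axes behave on a transect and scale with distance", {
  co <- data.frame(population = paste0("p", 1:12),
                   latitude = 60, longitude = seq(10, 32, 2))
  pc <- pcnm_axes(co)
  expect_lte(ncol(pc$vectors), 11)
  expect_true(all(pc$values > 0))
  # sinusoid-like: leading axis changes sign once along the transect
  expect_lte(sum(diff(sign(pc$vectors[, 1])) != 0), 2)
  # directions are unchanged under a doubled coordinate span around centre
  co2 <- co
  co2$longitude <- 21 + 2 * (co$longitude - 21)
  pc2 <- pcnm_axes(co2)
  cors <- abs(diag(cor(pc$vectors[, 1:3], pc2$vectors[, 1:3])))
  expect_true(all(cors > 0.99))
})

test_that("24 simulated populations yield ~15 positive PCNM axes", {
  env <- simulate_environment(sim_config(seed = 9))
  pc <- pcnm_axes(env$coords)
  expect_gte(ncol(pc$vectors), 12)
  expect_lte(ncol(pc$vectors), 18)
})

test_that("forward selection finds planted drivers and stops", {
  set.seed(31)
  k <- 40
  hits <- 0
  for (b in 1:5) {
    X <- matrix(rnorm(k * 10), k, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    B <- matrix(0, 10, 150)
    B[3, ] <- rnorm(150); B[7, ] <- rnorm(150)
    Y <- X %*% B + matrix(rnorm(k * 150, 0, 1), k, 150)
    sel <- forward_select(scale(Y, scale = FALSE), X, n_perm = 199)
    if (all(c("v3", "v7") %in% sel) && length(sel) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("forward selection returns empty on orthogonal noise", {
  set.seed(32)
  empties <- vapply(1:10, function(b) {
    Y <- sim_freqs(seed = 100 + b)
    X <- matrix(rnorm(24 * 6), 24, 6)
    length(forward_select(Y, X, n_perm = 99)) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.7)
})

test_that("duplicated candidates are never both selected", {
  set.seed(33)
  X <- matrix(rnorm(24 * 3), 24, 3)
  X <- cbind(X, dup = X[, 1])
  colnames(X) <- c("a", "b", "c", "dup")
  Y <- X[, 1] %*% t(rnorm(100)) + matrix(rnorm(2400, 0, 0.5), 24, 100)
  sel <- forward_select(scale(Y, scale = FALSE), X, n_perm = 199)
  expect_lt(sum(c("a", "dup") %in% sel), 2)
})

test_that("RDA constrained SS equals brute-force per-response OLS", {
  set.seed(34)
  k <- 20
  X <- matrix(rnorm(k * 3), k, 3)
  Y <- X %*% matrix(rnorm(3 * 80), 3, 80) + matrix(rnorm(k * 80), k, 80)
  Y <- scale(Y, scale = FALSE)
  r <- rda_gea(Y, X, n_perm = 0)
  fitted_ss <- sum(vapply(seq_len(ncol(Y)), function(j) {
    sum(fitted(lm(Y[, j] ~ X))^2)
  }, numeric(1)))
  expect_equal(sum(r$eig) * (k - 1), fitted_ss, tolerance = 1e-10)
  expect_equal(r$r2 * sum(Y^2), fitted_ss, tolerance = 1e-8)
  # eigenvalues are non-negative and non-increasing
  expect_true(all(r$eig >= -1e-12))
  expect_true(all(diff(r$eig) <= 1e-12))
  expect_lte(r$adj_r2, r$r2)
})

test_that("null RDA centers adjusted R^2 at zero", {
  adj <- vapply(1:20, function(b) {
    Y <- sim_freqs(seed = 200 + b)
    X <- matrix(rnorm(24 * 3), 24, 3)
    rda_gea(Y, X, n_perm = 0)$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.05)
})

test_that("partial RDA: conditioning on X itself zeroes the constrained part", {
  set.seed(35)
  Y <- sim_freqs(seed = 36)
  X <- matrix(rnorm(24 * 2), 24, 2)
  pr <- partial_rda(Y, X, Z = X, n_perm = 0)
  expect_lt(sum(pr$eig), 1e-20)
  # conditioning on a matrix orthogonal to X leaves the constrained
  # variance unchanged
  Z <- qr.Q(qr(cbind(1, X, matrix(rnorm(48), 24, 2))))[, 4:5]
  Xo <- qr.Q(qr(cbind(1, Z, X)))[, 4:5]  # X orthogonalized to (1, Z)
  r_plain <- rda_gea(Y, Xo, n_perm = 0)
  r_part <- partial_rda(Y, Xo, Z = Z, n_perm = 0)
  expect_equal(sum(r_part$eig), sum(r_plain$eig), tolerance = 1e-8)
})

test_that("variance partitioning is an exact adjusted-R^2 identity", {
  set.seed(37)
  k <- 24
  Xe <- matrix(rnorm(k * 2), k, 2)
  Xg <- matrix(rnorm(k * 2), k, 2)
  Y <- Xe %*% matrix(rnorm(2 * 120, 0, 0.6), 2, 120) +
    Xg %*% matrix(rnorm(2 * 120, 0, 0.4), 2, 120) +
    matrix(rnorm(k * 120), k, 120)
  Y <- scale(Y, scale = FALSE)
  vp <- variance_partition(Y, Xe, Xg)
  expect_equal(vp$env_only + vp$geo_only + vp$shared, vp$full_adj_r2,
               tolerance = 1e-10)
  # identical predictor sets: everything shared
  vp2 <- variance_partition(Y, Xe, Xe + 0)
  expect_lt(abs(vp2$env_only), 1e-10)
  expect_lt(abs(vp2$geo_only), 1e-10)
  # cross-check against vegan::varpart
  v <- vegan::varpart(Y, Xe, Xg)
  fr <- v$part$indfract$Adj.R.squared  # [a]=X1|X2, [b]=X2|X1, [c]=shared
  expect_equal(vp$env_only, fr[1], tolerance = 1e-8)
  expect_equal(vp$geo_only, fr[2], tolerance = 1e-8)
  expect_equal(vp$shared, fr[3], tolerance = 1e-8)
})

test_that("orthogonal known shares are recovered by the partition", {
  set.seed(38)
  k <- 40
  Q <- qr.Q(qr(matrix(rnorm(k * 5), k, 5)))
  Xe <- Q[, 1:2]; Xg <- Q[, 3:4]
  p <- 400
  Y <- sqrt(0.25) * Xe %*% matrix(rnorm(2 * p), 2, p) / sqrt(2 / k) +
    sqrt(0.15) * Xg %*% matrix(rnorm(2 * p), 2, p) / sqrt(2 / k) +
    sqrt(0.60) * matrix(rnorm(k * p), k, p)
  vp <- variance_partition(scale(Y, scale = FALSE), Xe, Xg)
  expect_lt(abs(vp$shared), 0.03)
  expect_lt(abs(vp$env_only - 0.25), 0.04)
  expect_lt(abs(vp$geo_only - 0.15), 0.04)
})

test_that("outlier scan: null loadings produce ~no BH discoveries", {
  set.seed(39)
  n_disc <- vapply(1:30, function(b) {
    L <- matrix(rnorm(3000 * 2), 3000, 2)
    fake <- structure(list(snp_loadings = L), class = "rda_result")
    sum(rda_outliers(fake, n_axes = 2)$outlier)
  }, numeric(1))
  expect_lte(mean(n_disc > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / 30))
})

test_that("outlier scan recovers planted high-loading loci", {
  set.seed(40)
  ok <- vapply(1:10, function(b) {
    L <- matrix(rnorm(5000 * 2), 5000, 2)
    L[1:20, 1] <- L[1:20, 1] + sample(c(-6, 6), 20, TRUE)
    fake <- structure(list(snp_loadings = L), class = "rda_result")
    out <- rda_outliers(fake, n_axes = 2)
    sum(out$outlier[1:20]) >= 18 && sum(out$outlier[-(1:20)]) <= 20
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("zero-loading loci are never outliers, sd3 mode flags extremes", {
  set.seed(41)
  L <- rbind(c(0, 0), matrix(rnorm(999 * 2), 999, 2))
  L[2, ] <- c(10, 0)
  fake <- structure(list(snp_loadings = L), class = "rda_result")
  out_m <- rda_outliers(fake, n_axes = 2)
  expect_false(out_m$outlier[1])
  out_s <- rda_outliers(fake, n_axes = 2, method = "sd3")
  expect_false(out_s$outlier[1])
  expect_true(out_s$outlier[2])
  expect_error(rda_outliers(fake, n_axes = 0), "n_axes")
})

test_that("population allele frequencies are centered and bounded", {
  cfg <- sim_config(n_pops = 5, n_per_pop = 10, n_snps = 50,
                    n_outlier_loci = 0, seed = 42)
  g <- simulate_genotypes(cfg)$genotypes
  f_raw <- pop_allele_freqs(g, center = FALSE)
  expect_true(all(f_raw >= 0 & f_raw <= 1))
  f_c <- pop_allele_freqs(g)
  expect_lt(max(abs(colMeans(f_c))), 1e-12)
})
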