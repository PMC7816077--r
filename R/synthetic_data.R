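#' Configuration for the synthetic genotype-environment-phenotype generator
#'
#' Defaults emulate the study system the pipeline was designed around: 24
#' populations of ~31 genotyped seedlings (~750 total) on a jittered
#' latitude/longitude grid spanning Fennoscandia into western Russia,
#' ~10 925 biallelic SNPs with near-zero differentiation (target F_ST
#' 0.004) plus a handful of strongly differentiated loci restricted to
#' "north-western" marginal populations, 68 climate variables collinear
#' with geography, and a polygenic frost-damage trait with within-population
#' marker heritability 0.56 and among-population Q_ST 0.8 on the latent
#' scale, scored 0-6 at 10 freezing time points.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population.
#' @param n_snps number of biallelic SNPs.
#' @param target_fst Balding-Nichols F parameter in `[0, 1)`.
#' @param n_outlier_loci number of strongly differentiated loci.
#' @param outlier_pops integer ids of the marginal ("NW") populations that
#'   carry the outlier allele at high frequency.
#' @param outlier_freq_shift allele-frequency shift added in outlier
#'   populations (clipped to `[0, 1]`).
#' @param lat_range,long_range degree ranges of the sampling grid.
#' @param env_lat_loading,env_long_loading SD of the per-variable latitude /
#'   longitude loadings of the climate variables.
#' @param env_noise_sd SD of the climate-variable noise term.
#' @param n_env_vars number of climate variables.
#' @param n_causal number of causal SNPs behind the damage trait.
#' @param h2_marker within-population marker heritability of the latent
#'   liability, in `(0, 1)`.
#' @param latent_sd total within-population latent SD on the log-link
#'   scale (sigma_W); 0.4 keeps expected scores inside the 0-6 range for
#'   realistic Q_ST targets.
#' @param qst_target among-population Q_ST of the latent liability.
#' @param ddi_timepoints number of freezing time points (days since
#'   dormancy initiation).
#' @param n_reps replications of the common-garden design.
#' @param edge_effect log-scale damage increase for seedlings on the
#'   freezer edge.
#' @param damage_model `"poisson"` (truncated Poisson on a log-linear
#'   latent predictor, matching the analysis model) or `"ordinal"`
#'   (threshold model on the latent scale, for mis-specification checks).
#' @param seed master seed; stage substreams derive from it via
#'   [seed_stream()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 24, n_per_pop = 31, n_snps = 10925,
                       target_fst = 0.004, n_outlier_loci = 10,
                       outlier_pops = 1:3, outlier_freq_shift = 0.9,
                       lat_range = c(57.5, 69.1), long_range = c(5, 52.3),
                       n_env_vars = 68, env_lat_loading = 1,
                       env_long_loading = 0.5, env_noise_sd = 0.3,
                       n_causal = 100, h2_marker = 0.56, qst_target = 0.8,
                       latent_sd = 0.4,
                       ddi_timepoints = 10, n_reps = 2, edge_effect = 0.1,
                       damage_model = c("poisson", "ordinal"), seed = 1) {
  damage_model <- match.arg(damage_model)
  cfg <- list(
    n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
    n_snps = as.integer(n_snps), target_fst = target_fst,
    n_outlier_loci = as.integer(n_outlier_loci),
    outlier_pops = as.integer(outlier_pops),
    outlier_freq_shift = outlier_freq_shift,
    lat_range = lat_range, long_range = long_range,
    n_env_vars = as.integer(n_env_vars),
    env_lat_loading = env_lat_loading,
    env_long_loading = env_long_loading, env_noise_sd = env_noise_sd,
    n_causal = as.integer(n_causal), h2_marker = h2_marker,
    qst_target = qst_target, latent_sd = latent_sd,
    ddi_timepoints = as.integer(ddi_timepoints),
    n_reps = as.integer(n_reps), edge_effect = edge_effect,
    damage_model = damage_model, seed = as.integer(seed)
  )
  if (cfg$n_pops < 1 || cfg$n_snps < 1) {
    stop("need at least one population and one site", call. = FALSE)
  }
  if (cfg$target_fst < 0 || cfg$target_fst >= 1) {
    stop("target_fst must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_outlier_loci > cfg$n_snps) {
    stop("n_outlier_loci exceeds n_snps", call. = FALSE)
  }
  if (cfg$n_outlier_loci == 0L) cfg$outlier_pops <- integer(0)
  if (length(cfg$outlier_pops) &&
      any(cfg$outlier_pops > cfg$n_pops | cfg$outlier_pops < 1)) {
    stop("outlier_pops must be existing population ids", call. = FALSE)
  }
  if (cfg$h2_marker <= 0 || cfg$h2_marker >= 1) {
    stop("h2_marker must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$qst_target < 0 || cfg$qst_target >= 1) {
    stop("qst_target must lie in [0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# internal: jittered-grid population coordinates, deterministic in the seed
sim_coords <- function(config) {
  set.seed(seed_stream(config$seed, 11L))
  k <- config$n_pops
  ncol_grid <- ceiling(sqrt(k))
  nrow_grid <- ceiling(k / ncol_grid)
  gx <- ((seq_len(k) - 1) %% ncol_grid + 0.5) / ncol_grid
  gy <- ((seq_len(k) - 1) %/% ncol_grid + 0.5) / nrow_grid
  jit <- function(n, w) stats::runif(n, -w, w)
  lat <- config$lat_range[1] +
    (gy + jit(k, 0.25 / nrow_grid)) * diff(config$lat_range)
  long <- config$long_range[1] +
    (gx + jit(k, 0.25 / ncol_grid)) * diff(config$long_range)
  data.frame(population = paste0("pop", seq_len(k)),
             latitude = lat, longitude = long,
             stringsAsFactors = FALSE)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per-site ancestral frequency p ~ U(0.05, 0.95); population frequencies
#' Beta(p(1-F)/F, (1-p)(1-F)/F) for F = `target_fst` (> 0), the ancestral
#' frequency exactly when F = 0; genotypes Binomial(2, p_pop). Designated
#' outlier loci emulate rare alleles swept to high frequency in marginal
#' populations: their ancestral frequency is drawn rare (U(0.01, 0.10)), the
#' outlier populations get p + `outlier_freq_shift` clipped to `[0, 1]`, and
#' all other populations keep the ancestral frequency.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [geno_matrix()] carrying synthetic GQ/DP)
#'   and `truth` (ancestral and population frequencies, outlier ids,
#'   population coordinates).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_stream(config$seed, 1L))
  k <- config$n_pops; L <- config$n_snps; F <- config$target_fst
  p_anc <- stats::runif(L, 0.05, 0.95)
  outlier_ids <- integer(0)
  if (config$n_outlier_loci > 0 && length(config$outlier_pops) > 0) {
    outlier_ids <- sort(sample.int(L, config$n_outlier_loci))
    p_anc[outlier_ids] <- stats::runif(config$n_outlier_loci, 0.01, 0.10)
  }
  if (F > 0) {
    shape1 <- p_anc * (1 - F) / F
    shape2 <- (1 - p_anc) * (1 - F) / F
    pop_freqs <- matrix(stats::rbeta(k * L, rep(shape1, each = k),
                                     rep(shape2, each = k)), nrow = k)
  } else {
    pop_freqs <- matrix(rep(p_anc, each = k), nrow = k)
  }
  if (length(outlier_ids)) {
    pop_freqs[, outlier_ids] <- matrix(rep(p_anc[outlier_ids], each = k),
                                       nrow = k)
    pop_freqs[config$outlier_pops, outlier_ids] <-
      pmin(1, pmax(0, rep(p_anc[outlier_ids] + config$outlier_freq_shift,
                          each = length(config$outlier_pops))))
  }
  n <- k * config$n_per_pop
  pop_of <- rep(seq_len(k), each = config$n_per_pop)
  calls <- matrix(stats::rbinom(n * L, 2L, pop_freqs[pop_of, ]),
                  nrow = n, ncol = L)
  storage.mode(calls) <- "integer"
  sites <- data.frame(
    id = paste0("snp", seq_len(L)),
    chrom = paste0("scaffold_", 1 + (seq_len(L) - 1) %/% 200),
    pos = 1000L + ((seq_len(L) - 1L) %% 200L) * 350L,
    ref = "A", alt = "G", biallelic = TRUE,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    id = sprintf("ind_%03d_%03d", pop_of, rep(seq_len(config$n_per_pop), k)),
    population = paste0("pop", pop_of),
    stringsAsFactors = FALSE
  )
  # synthetic call quality: high-GQ, moderate-depth GBS-like calls
  gq <- matrix(pmin(99L, stats::rpois(n * L, 60)), n, L)
  dp <- matrix(pmax(1L, stats::rpois(n * L, 30)), n, L)
  truth <- list(
    ancestral_freqs = p_anc,
    pop_freqs = pop_freqs,
    outlier_ids = outlier_ids,
    coords = sim_coords(config)
  )
  list(genotypes = geno_matrix(calls, sites, samples, gq = gq, dp = dp),
       truth = truth)
}

#' Simulate climate variables collinear with geography
#'
#' Each variable is `a_v * lat + b_v * long + N(0, env_noise_sd)` on
#' standardized coordinates, with loadings drawn per variable so the set is
#' collinear with geography. The first variable is a growing-degree-days
#' style summary ("GDD5") with a strong negative latitude loading; the
#' second ("GDD0") is its slightly perturbed sibling.
#'
#' @param config a [sim_config()].
#' @return list with `env` (populations x variables matrix) and `coords`
#'   (population latitude/longitude, identical to the genotype stage's).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coords <- sim_coords(config)
  set.seed(seed_stream(config$seed, 2L))
  k <- config$n_pops; m <- config$n_env_vars
  zl <- as.numeric(scale(coords$latitude))
  zg <- as.numeric(scale(coords$longitude))
  a <- stats::rnorm(m, 0, config$env_lat_loading)
  b <- stats::rnorm(m, 0, config$env_long_loading)
  if (m >= 1) { a[1] <- -2.0; b[1] <- 0.2 }  # GDD5-like
  if (m >= 2) { a[2] <- -1.8; b[2] <- 0.3 }  # GDD0-like
  env <- outer(zl, a) + outer(zg, b) +
    matrix(stats::rnorm(k * m, 0, config$env_noise_sd), k, m)
  colnames(env) <- c(if (m >= 1) "GDD5", if (m >= 2) "GDD0",
                     if (m > 2) sprintf("env_%02d", seq_len(m - 2) + 2))
  rownames(env) <- coords$population
  list(env = env, coords = coords)
}

#' Simulate seedling freeze-damage scores
#'
#' A latent liability per seedling combines a population adaptive shift
#' (linear in latitude, scaled so the latent between/within variance ratio
#' hits `qst_target`), additive causal-SNP effects (scaled so the
#' within-population genetic share of latent variance is `h2_marker`), and
#' Gaussian noise. Each seedling is frozen once at one of the configured
#' time points within a replication; expected damage declines with days
#' since dormancy initiation and increases on the freezer edge. Observed
#' scores are Poisson draws on the exponentiated predictor truncated to
#' 0-6 (or ordinal-threshold draws when `damage_model = "ordinal"`).
#'
#' @param config a [sim_config()].
#' @param genotypes a [geno_matrix()] from [simulate_genotypes()].
#' @param truth the matching truth list; returned augmented with causal ids
#'   and effects, realized latent variance components, `true_qst` (exactly
#'   sigma2_B / (sigma2_B + 2 sigma2_W) of the stored components) and
#'   `true_h2`.
#' @return list with `damage` (data.frame seedling, population, rep, ddi,
#'   kantf, score), `truth`, and `latent` (per-seedling latent liabilities,
#'   for generator diagnostics).
#' @export
simulate_damage <- function(config, genotypes, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$h2_marker <= 0 || config$h2_marker >= 1) {
    stop("h2_marker must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed_stream(config$seed, 3L))
  calls <- genotypes$calls
  n <- nrow(calls)
  pop <- genotypes$samples$population
  coords <- truth$coords
  lat <- coords$latitude[match(pop, coords$population)]

  # causal architecture: total within-pop latent variance latent_sd^2,
  # of which a fraction h2_marker is additive-genetic
  sigma_w2 <- config$latent_sd^2
  causal_ids <- integer(0); causal_effects <- numeric(0)
  gv <- numeric(n)
  if (config$n_causal > 0) {
    pool <- setdiff(seq_len(ncol(calls)), truth$outlier_ids)
    causal_ids <- sort(sample(pool, min(config$n_causal, length(pool))))
    causal_effects <- stats::rnorm(length(causal_ids))
    G <- calls[, causal_ids, drop = FALSE]
    G[is.na(G)] <- 0L
    gv <- as.numeric(G %*% causal_effects)
    v_raw <- mean(tapply(gv, pop, stats::var), na.rm = TRUE)
    if (v_raw > 0) {
      scl <- sqrt(config$h2_marker * sigma_w2 / v_raw)
      causal_effects <- causal_effects * scl
      gv <- gv * scl
    }
  }
  v_g <- if (config$n_causal > 0) config$h2_marker * sigma_w2 else 0
  sigma_e2 <- sigma_w2 - v_g
  true_h2 <- v_g / sigma_w2

  # population adaptive shift: linear in latitude, scaled so the realized
  # between-pop variance hits the Q_ST target exactly
  q <- config$qst_target
  pop_lat <- coords$latitude - mean(coords$latitude)
  if (q > 0 && stats::sd(pop_lat) > 0) {
    sigma_b2 <- 2 * sigma_w2 * q / (1 - q)
    shift <- -pop_lat / stats::sd(pop_lat) * sqrt(sigma_b2)
  } else {
    sigma_b2 <- 0
    shift <- rep(0, config$n_pops)
  }
  names(shift) <- coords$population
  a_pop <- shift[pop]

  gv_c <- gv - mean(gv)
  latent <- a_pop + gv_c + stats::rnorm(n, 0, sqrt(sigma_e2))

  # design: one freeze per seedling at one DDI time point
  ddi_days <- 7L + 3L * (seq_len(config$ddi_timepoints) - 1L)
  ddi <- sample(rep_len(ddi_days, n))
  repl <- sample(rep_len(seq_len(config$n_reps), n))
  kantf <- stats::rbinom(n, 1L, 0.3)
  z_ddi <- as.numeric(scale(ddi))
  beta0 <- log(1.5)
  beta_ddi <- -0.54
  eta <- beta0 + beta_ddi * z_ddi + config$edge_effect * kantf + latent

  if (config$damage_model == "poisson") {
    score <- pmin(stats::rpois(n, exp(eta)), 6L)
  } else {
    cuts <- stats::qnorm(seq(1, 6) / 7, sd = 2)
    score <- findInterval(eta - beta0 + stats::rnorm(n, 0, 1), cuts)
  }
  damage <- data.frame(
    seedling = genotypes$samples$id,
    population = pop,
    rep = paste0("rep", repl),
    ddi = ddi,
    kantf = kantf,
    score = as.integer(score),
    stringsAsFactors = FALSE
  )
  truth$causal_ids <- causal_ids
  truth$causal_effects <- causal_effects
  truth$true_sigmaB2 <- sigma_b2
  truth$true_sigmaW2 <- sigma_w2
  truth$true_qst <- if (sigma_b2 + sigma_w2 > 0)
    sigma_b2 / (sigma_b2 + 2 * sigma_w2) else 0
  truth$true_h2 <- true_h2
  truth$pop_shift <- shift
  list(damage = damage, truth = truth, latent = latent)
}

#' Write a simulated dataset to disk
#'
#' Genotypes as minimal VCF 4.2 (GT:GQ:DP), sample-population map,
#' environment and damage tables as TSV, truth as JSON.
#'
#' @param sim list with `genotypes`, `env`, `coords`, `damage`, `truth`
#'   components (any subset).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$genotypes)) {
    write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
    tsv(sim$genotypes$samples, "samples.tsv")
  }
  if (!is.null(sim$env)) {
    tsv(data.frame(population = rownames(sim$env), sim$env,
                   check.names = FALSE), "environment.tsv")
  }
  if (!is.null(sim$coords)) tsv(sim$coords, "coords.tsv")
  if (!is.null(sim$damage)) tsv(sim$damage, "damage.tsv")
  if (!is.null(sim$truth)) {
    tr <- sim$truth
    tr$pop_freqs <- NULL  # bulky; reconstructable from the seed
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
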