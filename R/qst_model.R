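# Hierarchical Poisson model of seedling freeze-damage scores.
#
# score_i ~ Poisson(lambda_i)
# log lambda_i = x_i' beta + u_pop(i) + v_pop:rep(i) + e_i
# u ~ N(0, sigma2_B), v ~ N(0, sigma2_rep), e ~ N(0, sigma2_W)
#
# The seedling-level latent effect e carries the within-population latent
# variance (a pure Poisson has none free), so Q_ST is defined on the
# log-link scale as sigma2_B / (sigma2_B + 2 h2 sigma2_W).
#
# Sampler: Metropolis-within-Gibbs. Variances have conjugate inverse-gamma
# updates; latent effects and fixed effects use random-walk Metropolis with
# step sizes adapted during burn-in.

#' Standardize experimental and geographic covariates
#'
#' Centers and scales (sample SD) the numeric covariates used by the damage
#' model, storing the scaling so standardized effects can be back-converted
#' to per-day / per-degree units (effect / SD).
#'
#' @param table data.frame containing some of `ddi`, `latitude`,
#'   `longitude`.
#' @param cols columns to standardize (defaults to whichever of the three
#'   are present).
#' @return `table` with standardized columns and a `"scaling"` attribute
#'   (data.frame variable, center, scale). Standardizing twice is a no-op.
#' @export
standardize_covariates <- function(table,
                                   cols = intersect(c("ddi", "latitude",
                                                      "longitude"),
                                                    names(table))) {
  prior <- attr(table, "scaling")
  done <- if (is.null(prior)) character() else prior$variable
  recs <- list()
  for (v in setdiff(cols, done)) {
    x <- table[[v]]
    if (!is.numeric(x)) stop(sprintf("'%s' is not numeric", v), call. = FALSE)
    s <- stats::sd(x)
    if (s == 0) stop(sprintf("'%s' has zero SD", v), call. = FALSE)
    m <- mean(x)
    table[[v]] <- (x - m) / s
    recs[[v]] <- data.frame(variable = v, center = m, scale = s,
                            stringsAsFactors = FALSE)
  }
  attr(table, "scaling") <- rbind(prior, do.call(rbind, recs))
  table
}

#' Back-convert a standardized effect to natural units
#'
#' @param effect effect per 1 SD of the standardized covariate.
#' @param scaling the `"scaling"` attribute from
#'   [standardize_covariates()].
#' @param variable which covariate.
#' @return effect per natural unit (per day, per degree).
#' @export
effect_per_unit <- function(effect, scaling, variable) {
  i <- match(variable, scaling$variable)
  if (is.na(i)) stop("variable not found in scaling record", call. = FALSE)
  effect / scaling$scale[i]
}

# internal: inverse-gamma draw for a variance given sum of squares
.draw_var <- function(ss, k, a0 = 0.01, b0 = 0.01) {
  1 / stats::rgamma(1, a0 + k / 2, b0 + ss / 2)
}

#' Fit the hierarchical Poisson damage model by MCMC
#'
#' @param damage data.frame with columns `population, rep, ddi, kantf,
#'   score` (integer scores 0-6).
#' @param coords optional data.frame `population, latitude, longitude`,
#'   required when `geography = "fixed"`.
#' @param geography `"none"` keeps all among-population signal in the
#'   population effects (the Q_ST-estimation default); `"fixed"` adds
#'   standardized latitude/longitude main effects and their interactions
#'   with each other and with DDI (the effect-structure model).
#' @param h2 heritability used for the derived Q_ST draws (1 treats the
#'   whole within-population latent variance as genetic).
#' @param iters,burnin,thin MCMC controls (post-burn-in draws =
#'   `(iters - burnin) / thin`).
#' @param seed RNG seed.
#' @param prior_sd fixed-effect prior SD (Normal(0, prior_sd^2)).
#' @param ceiling treatment of the top score: `"censored"` (default)
#'   models score 6 ("all needles discolored") as the right-censored
#'   category 6-or-worse, P(score = 6) = P(Poisson >= 6); `"ignore"`
#'   treats scores as unbounded Poisson counts (the ceiling then biases
#'   the within-population variance downward).
#' @return a `qst_posterior` list: `beta` (draws x effects), `u` (draws x
#'   populations), `sigmaB2`, `sigmaRep2`, `sigmaW2`, `qst` (per-draw
#'   sigma2_B / (sigma2_B + 2 h2 sigma2_W)), `qst_estimate`, `qst_hpdi`,
#'   `h2`, `scaling`, `diagnostics` (split-Rhat and ESS per variance),
#'   `populations`, `accept` rates.
#' @export
fit_damage_model <- function(damage, coords = NULL,
                             geography = c("none", "fixed"), h2 = 1,
                             iters = 4000, burnin = 2000, thin = 2,
                             seed = 1, prior_sd = 10,
                             ceiling = c("censored", "ignore")) {
  geography <- match.arg(geography)
  ceiling <- match.arg(ceiling)
  .need_cols(damage, c("population", "rep", "ddi", "kantf", "score"),
             "damage table")
  score <- damage$score
  if (any(is.na(score)) || any(score != round(score)) ||
      any(score < 0 | score > 6)) {
    stop("scores must be integers in 0..6", call. = FALSE)
  }
  if (length(unique(damage$population)) < 2) {
    stop("need at least two populations", call. = FALSE)
  }
  set.seed(seed)

  tab <- damage
  if (geography == "fixed") {
    if (is.null(coords)) stop("coords required for geography = 'fixed'",
                              call. = FALSE)
    .need_cols(coords, c("population", "latitude", "longitude"),
               "coords table")
    i <- match(tab$population, coords$population)
    tab$latitude <- coords$latitude[i]
    tab$longitude <- coords$longitude[i]
  }
  tab <- standardize_covariates(tab)
  scaling <- attr(tab, "scaling")

  X <- cbind(intercept = 1, s_ddi = tab$ddi, kantf = as.numeric(tab$kantf))
  if (geography == "fixed") {
    X <- cbind(X, s_lat = tab$latitude, s_long = tab$longitude,
               lat_x_long = tab$latitude * tab$longitude,
               lat_x_ddi = tab$latitude * tab$ddi,
               long_x_ddi = tab$longitude * tab$ddi)
  }
  n <- length(score)
  pop_f <- factor(tab$population)
  pr_f <- factor(paste(tab$population, tab$rep, sep = ":"))
  pop_i <- as.integer(pop_f); npop <- nlevels(pop_f)
  pr_i <- as.integer(pr_f); npr <- nlevels(pr_f)

  # state
  beta <- rep(0, ncol(X)); beta[1] <- log(mean(score) + 0.05)
  u <- rep(0, npop); v <- rep(0, npr); e <- rep(0, n)
  s2b <- 0.5; s2r <- 0.1; s2w <- 0.5
  eta_fix <- as.numeric(X %*% beta)
  step_e <- 0.6; step_u <- 0.3; step_v <- 0.3
  step_b <- rep(0.1, ncol(X))
  acc <- list(e = 0, u = 0, v = 0, b = rep(0, ncol(X)))

  n_keep <- floor((iters - burnin) / thin)
  keep <- list(
    beta = matrix(NA_real_, n_keep, ncol(X),
                  dimnames = list(NULL, colnames(X))),
    u = matrix(NA_real_, n_keep, npop, dimnames = list(NULL, levels(pop_f))),
    sigmaB2 = numeric(n_keep), sigmaRep2 = numeric(n_keep),
    sigmaW2 = numeric(n_keep)
  )
  ki <- 0L
  tune <- function(step, rate, target) {
    step * exp(0.6 * (rate - target))
  }

  # observation log-likelihood (constants in y! dropped): plain Poisson
  # terms, with score 6 treated as right-censored ("6 or worse") unless
  # ceiling = "ignore"
  capped <- if (ceiling == "censored") score == 6L else rep(FALSE, n)
  any_cap <- any(capped)
  loglik_vec <- function(eta) {
    ll <- score * eta - exp(eta)
    if (any_cap) {
      ll[capped] <- stats::ppois(5, exp(eta[capped]), lower.tail = FALSE,
                                 log.p = TRUE)
    }
    ll
  }

  for (it in seq_len(iters)) {
    eta <- eta_fix + u[pop_i] + v[pr_i] + e
    ll_cur <- loglik_vec(eta)

    # seedling latent effects (independent given the rest): vectorized MH
    e_prop <- e + stats::rnorm(n, 0, step_e)
    d_eta <- e_prop - e
    lr <- loglik_vec(eta + d_eta) - ll_cur -
      (e_prop^2 - e^2) / (2 * s2w)
    take <- log(stats::runif(n)) < lr
    e[take] <- e_prop[take]
    eta[take] <- eta[take] + d_eta[take]
    ll_cur <- loglik_vec(eta)
    a_e <- mean(take)

    # population effects, jointly vectorized through per-group sums
    u_prop <- u + stats::rnorm(npop, 0, step_u)
    d_obs <- (u_prop - u)[pop_i]
    lr <- as.numeric(rowsum(loglik_vec(eta + d_obs) - ll_cur, pop_i)) -
      (u_prop^2 - u^2) / (2 * s2b)
    take <- log(stats::runif(npop)) < lr
    u[take] <- u_prop[take]
    eta <- eta_fix + u[pop_i] + v[pr_i] + e
    ll_cur <- loglik_vec(eta)
    a_u <- mean(take)

    # replication-within-population effects
    v_prop <- v + stats::rnorm(npr, 0, step_v)
    d_obs <- (v_prop - v)[pr_i]
    lr <- as.numeric(rowsum(loglik_vec(eta + d_obs) - ll_cur, pr_i)) -
      (v_prop^2 - v^2) / (2 * s2r)
    take <- log(stats::runif(npr)) < lr
    v[take] <- v_prop[take]
    eta <- eta_fix + u[pop_i] + v[pr_i] + e
    ll_cur <- loglik_vec(eta)
    a_v <- mean(take)

    # fixed effects, one at a time
    a_b <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      db <- stats::rnorm(1, 0, step_b[j])
      xj <- X[, j]
      lr <- sum(loglik_vec(eta + xj * db) - ll_cur) -
        ((beta[j] + db)^2 - beta[j]^2) / (2 * prior_sd^2)
      if (log(stats::runif(1)) < lr) {
        beta[j] <- beta[j] + db
        eta <- eta + xj * db
        ll_cur <- loglik_vec(eta)
        a_b[j] <- 1
      }
    }
    eta_fix <- as.numeric(X %*% beta)

    # variances: conjugate inverse-gamma (centered step) ...
    s2b <- .draw_var(sum(u^2), npop)
    s2r <- .draw_var(sum(v^2), npr)
    s2w <- .draw_var(sum(e^2), n)

    # ... interwoven with a non-centered rescaling move per block
    # (effects and their variance move together, breaking the funnel
    # between a latent block and its variance)
    eta_base <- eta_fix + u[pop_i] + v[pr_i] + e
    ll_base <- loglik_vec(eta_base)
    rescale <- function(block_eta, s2, step = 0.6) {
      f2 <- exp(stats::rnorm(1, 0, step))
      f <- sqrt(f2)
      d_eta <- (f - 1) * block_eta
      lac <- sum(loglik_vec(eta_base + d_eta) - ll_base) +
        (-0.01 - 1) * log(f2) - 0.01 / (s2 * f2) + 0.01 / s2 + log(f2)
      if (log(stats::runif(1)) < lac) list(f = f, s2 = s2 * f2)
      else NULL
    }
    rs <- rescale(e, s2w)
    if (!is.null(rs)) {
      e <- e * rs$f; s2w <- rs$s2
      eta_base <- eta_fix + u[pop_i] + v[pr_i] + e
      ll_base <- loglik_vec(eta_base)
    }
    rs <- rescale(u[pop_i], s2b)
    if (!is.null(rs)) {
      u <- u * rs$f; s2b <- rs$s2
      eta_base <- eta_fix + u[pop_i] + v[pr_i] + e
      ll_base <- loglik_vec(eta_base)
    }
    rs <- rescale(v[pr_i], s2r)
    if (!is.null(rs)) { v <- v * rs$f; s2r <- rs$s2 }

    if (it <= burnin && it %% 25 == 0) {
      step_e <- tune(step_e, a_e, 0.44)
      step_u <- tune(step_u, a_u, 0.44)
      step_v <- tune(step_v, a_v, 0.44)
      step_b <- tune(step_b, a_b, 0.35)
    }
    if (it > burnin) {
      acc$e <- acc$e + a_e; acc$u <- acc$u + a_u; acc$v <- acc$v + a_v
      acc$b <- acc$b + a_b
      if ((it - burnin) %% thin == 0) {
        ki <- ki + 1L
        keep$beta[ki, ] <- beta
        keep$u[ki, ] <- u
        keep$sigmaB2[ki] <- s2b
        keep$sigmaRep2[ki] <- s2r
        keep$sigmaW2[ki] <- s2w
      }
    }
  }

  qst <- keep$sigmaB2 / (keep$sigmaB2 + 2 * h2 * keep$sigmaW2)
  diag_of <- function(x) c(rhat = split_rhat(x), ess = ess_acf(x))
  diagnostics <- rbind(sigmaB2 = diag_of(keep$sigmaB2),
                       sigmaW2 = diag_of(keep$sigmaW2),
                       qst = diag_of(qst))
  if (any(diagnostics[, "rhat"] >= 1.1, na.rm = TRUE)) {
    warning("split-Rhat >= 1.1 on a variance component; ",
            "increase iters/burnin or thin more")
  }
  n_post <- iters - burnin
  structure(list(
    beta = keep$beta, u = keep$u, sigmaB2 = keep$sigmaB2,
    sigmaRep2 = keep$sigmaRep2, sigmaW2 = keep$sigmaW2,
    qst = qst, qst_estimate = mean(qst), qst_hpdi = hpdi(qst),
    h2 = h2, scaling = scaling, populations = levels(pop_f),
    diagnostics = diagnostics,
    accept = list(e = acc$e / n_post, u = acc$u / n_post,
                  v = acc$v / n_post, beta = acc$b / n_post),
    geography = geography
  ), class = "qst_posterior")
}

#' @export
print.qst_posterior <- function(x, ...) {
  cat(sprintf(
    "<qst_posterior> %d draws, %d populations (geography: %s)\n",
    length(x$qst), length(x$populations), x$geography))
  cat(sprintf("  Q_ST (h2 = %g): %.3f [%.3f, %.3f] 95%% HPDI\n",
              x$h2, x$qst_estimate, x$qst_hpdi[1], x$qst_hpdi[2]))
  cat(sprintf("  sigma2_B: %.3f   sigma2_W: %.3f\n",
              mean(x$sigmaB2), mean(x$sigmaW2)))
  invisible(x)
}

# internal: split-Rhat on a single chain (first half vs second half)
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  ch <- cbind(x[seq_len(n)], x[seq(n + 1, 2 * n)])
  w <- mean(apply(ch, 2, stats::var))
  b <- n * stats::var(colMeans(ch))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# internal: effective sample size by initial positive sequence of the ACF
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}
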