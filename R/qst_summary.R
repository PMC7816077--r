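# Posterior summaries of the damage model: the Q_ST formula and its
# inverse, least-squares population means, pairwise Q_ST, environmental
# PCA distance, trait-climate correlations, and cline fits.

#' Q_ST from variance components
#'
#' Q_ST = sigma2_B / (sigma2_B + 2 h2 sigma2_W).
#'
#' @param sigmaB2 between-population variance (>= 0).
#' @param sigmaW2 within-population variance (>= 0).
#' @param h2 heritability in `(0, 1]` (1 treats the full within-population
#'   variance as additive-genetic).
#' @return Q_ST (vectorized over the variance arguments).
#' @export
qst_point <- function(sigmaB2, sigmaW2, h2 = 1) {
  stopifnot(all(sigmaB2 >= 0), all(sigmaW2 >= 0), h2 > 0, h2 <= 1)
  if (any(sigmaB2 + sigmaW2 == 0)) {
    stop("Q_ST undefined when both variances are zero", call. = FALSE)
  }
  sigmaB2 / (sigmaB2 + 2 * h2 * sigmaW2)
}

#' Invert the Q_ST formula for the variance ratio
#'
#' Given Q_ST obtained at heritability `h2`, returns the implied
#' between/within variance ratio sigma2_B / sigma2_W = 2 h2 Q / (1 - Q),
#' so the estimate can be re-evaluated at another heritability:
#' `qst_point(qst_invert(q, 1), 1, h2 = h2_new)`.
#'
#' @param qst Q_ST in `[0, 1)`.
#' @param h2 heritability at which `qst` was obtained.
#' @return sigma2_B / sigma2_W.
#' @export
qst_invert <- function(qst, h2 = 1) {
  stopifnot(all(qst >= 0), all(qst < 1), h2 > 0, h2 <= 1)
  2 * h2 * qst / (1 - qst)
}

#' Least-squares population means of damage
#'
#' Model-adjusted population means with experimental covariates held at
#' their reference (standardized zero) values: per draw,
#' exp(intercept + u_pop + sigma2_W / 2) on the response scale (the
#' lognormal correction integrates the seedling-level latent effect out),
#' or intercept + u_pop on the link scale; then averaged over draws.
#'
#' @param posterior a `qst_posterior` from [fit_damage_model()].
#' @param scale response (default) or link scale.
#' @return named numeric vector of adjusted means per population.
#' @export
ls_means <- function(posterior, scale = c("response", "link")) {
  scale <- match.arg(scale)
  b0 <- posterior$beta[, "intercept"]
  lin <- posterior$u + b0
  if (scale == "response") {
    colMeans(exp(lin + posterior$sigmaW2 / 2))
  } else {
    colMeans(lin)
  }
}

#' Pairwise Q_ST between populations
#'
#' Per draw, the between-population variance for a pair is half the squared
#' difference of the two population effects, (u_i - u_j)^2 / 2, combined
#' with that draw's sigma2_W in the Q_ST formula; the posterior mean matrix
#' is returned.
#'
#' @param posterior a `qst_posterior`.
#' @param h2 heritability (defaults to the one stored in the posterior).
#' @return symmetric population x population matrix with zero diagonal.
#' @export
pairwise_qst <- function(posterior, h2 = posterior$h2) {
  u <- posterior$u
  k <- ncol(u)
  m <- matrix(0, k, k, dimnames = list(colnames(u), colnames(u)))
  denom_w <- 2 * h2 * posterior$sigmaW2
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      sb <- (u[, i] - u[, j])^2 / 2
      m[i, j] <- m[j, i] <- mean(sb / (sb + denom_w))
    }
  }
  m
}

#' Environmental PCA distance between populations
#'
#' PCA of the per-variable standardized environment matrix; the minimal
#' number of leading axes reaching `cum_var` cumulative variance is
#' retained and pairwise Euclidean distances are computed on the retained
#' scores.
#'
#' @param env populations x variables matrix.
#' @param cum_var retained cumulative-variance threshold (default 0.80).
#' @return list: `distance` (symmetric matrix), `n_axes`, `scores`,
#'   `var_explained` (per axis), `cum_var_retained`.
#' @export
env_pca_distance <- function(env, cum_var = 0.80) {
  if (nrow(env) < 2) stop("need at least two populations", call. = FALSE)
  keep <- apply(env, 2, stats::sd) > 0
  if (!any(keep)) {
    # identical environments everywhere: zero distance, nothing retained
    d <- matrix(0, nrow(env), nrow(env),
                dimnames = list(rownames(env), rownames(env)))
    return(list(distance = d, n_axes = 0L, scores = NULL,
                var_explained = numeric(0), cum_var_retained = 0))
  }
  pc <- stats::prcomp(env[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- which(cumsum(ve) >= cum_var)[1]
  if (is.na(n_axes)) n_axes <- length(ve)
  sc <- pc$x[, seq_len(n_axes), drop = FALSE]
  d <- as.matrix(stats::dist(sc))
  rownames(d) <- colnames(d) <- rownames(env)
  list(distance = d, n_axes = n_axes, scores = sc, var_explained = ve,
       cum_var_retained = sum(ve[seq_len(n_axes)]))
}

#' Squared Spearman correlations of adjusted damage with climate
#'
#' rho^2 between the least-squares population means and every
#' environmental variable, with latitude and longitude appended, ranked
#' decreasing. Ties get average ranks (the default of [stats::cor()]'s
#' Spearman method).
#'
#' @param ls_means named vector of adjusted damage means (one per
#'   population).
#' @param env populations x variables matrix (rows matched to
#'   `names(ls_means)` by rowname).
#' @param coords optional data.frame `population, latitude, longitude`.
#' @return data.frame variable, rho, rho2, sorted by rho2 decreasing.
#' @export
trait_climate_correlations <- function(ls_means, env, coords = NULL) {
  if (length(ls_means) < 5) stop("need >= 5 populations", call. = FALSE)
  X <- env[match(names(ls_means), rownames(env)), , drop = FALSE]
  if (!is.null(coords)) {
    i <- match(names(ls_means), coords$population)
    X <- cbind(X, latitude = coords$latitude[i],
               longitude = coords$longitude[i])
  }
  rho <- apply(X, 2, function(v)
    suppressWarnings(stats::cor(ls_means, v, method = "spearman")))
  out <- data.frame(variable = colnames(X), rho = rho, rho2 = rho^2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$rho2), ]
}

#' Fit a linear or sigmoid cline to adjusted population means
#'
#' Linear: OLS. Sigmoid: four-parameter logistic
#' y = lower + (upper - lower) / (1 + exp((xmid - x) / scal)),
#' fitted by Levenberg-Marquardt nonlinear least squares from a grid of
#' starting values (both signs of `scal`, several midpoints). Adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1) with p = 1 (linear) or
#' 3 (sigmoid) non-baseline parameters.
#'
#' @param y response (adjusted damage means).
#' @param x predictor (latitude, GDD5, ...).
#' @param model `"linear"` or `"sigmoid"`.
#' @return list: model, coefficients, fitted, r2, adj_r2 (and `fit`, the
#'   underlying fit object).
#' @export
fit_cline <- function(y, x, model = c("linear", "sigmoid")) {
  model <- match.arg(model)
  n <- length(y)
  stopifnot(length(x) == n)
  if (model == "linear") {
    if (n < 3) stop("too few populations for a linear fit", call. = FALSE)
    fit <- stats::lm(y ~ x)
    r2 <- summary(fit)$r.squared
    return(list(model = "linear", coefficients = stats::coef(fit),
                fitted = stats::fitted(fit), r2 = r2,
                adj_r2 = .adj_r2(r2, n, 1), fit = fit))
  }
  if (n < 5) stop("too few populations for a 4-parameter fit",
                  call. = FALSE)
  dat <- data.frame(x = x, y = y)
  rng <- range(x)
  starts <- expand.grid(
    lower = min(y), upper = max(y),
    xmid = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    scal = c(1, -1) * diff(rng) / 5
  )
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lower + (upper - lower) / (1 + exp((xmid - x) / scal)),
        data = dat, start = as.list(starts[i, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) {
    stop("sigmoid fit failed to converge from any start", call. = FALSE)
  }
  r2 <- 1 - best_rss / sum((y - mean(y))^2)
  list(model = "sigmoid", coefficients = stats::coef(best),
       fitted = stats::fitted(best), r2 = r2,
       adj_r2 = .adj_r2(r2, n, 3), fit = best)
}
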