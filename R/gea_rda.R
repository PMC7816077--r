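# Genotype-environment association: PCNM spatial predictors, forward
# selection, (partial) RDA of population allele frequencies, variance
# partitioning between environment and geography, and an RDA-axis outlier
# scan. Ordination machinery is vegan's; the Mahalanobis outlier scan with
# genomic-inflation rescaling is implemented here.

#' Population allele-frequency matrix
#'
#' Per-population alternate-allele frequency from non-missing calls;
#' optionally column-centered (the RDA response convention used
#' throughout: centered, unscaled, so loadings keep frequency-shift
#' units).
#'
#' @param g a [geno_matrix()].
#' @param center column-center the matrix.
#' @return populations x sites numeric matrix.
#' @export
pop_allele_freqs <- function(g, center = TRUE) {
  pop <- g$samples$population
  cnt <- rowsum(ifelse(is.na(g$calls), 0, g$calls), pop)
  nok <- rowsum((!is.na(g$calls)) + 0, pop)
  f <- cnt / (2 * nok)
  f[nok == 0] <- NA
  if (center) f <- scale(f, center = TRUE, scale = FALSE)
  f
}

#' Spatial eigenvector (PCNM) predictors
#'
#' Great-circle distances between population coordinates are truncated at
#' `truncation` (default: the longest edge of the minimum spanning tree),
#' larger distances replaced by 4x the truncation, the matrix
#' double-centered and eigendecomposed; eigenvectors with positive
#' eigenvalues are returned in decreasing eigenvalue order.
#'
#' @param coords data.frame `population, latitude, longitude` (>= 3
#'   distinct locations).
#' @param truncation distance threshold in km, or NULL for the MST default.
#' @return list: `vectors` (populations x axes), `values` (positive
#'   eigenvalues), `truncation` (km used).
#' @export
pcnm_axes <- function(coords, truncation = NULL) {
  .need_cols(coords, c("population", "latitude", "longitude"), "coords")
  if (nrow(coords) < 3) stop("need >= 3 populations", call. = FALSE)
  xy <- cbind(coords$longitude, coords$latitude)
  d <- geosphere::distm(xy) / 1000  # km
  if (any(d[upper.tri(d)] == 0)) {
    warning("coincident coordinates; jittering by ~1 km")
    xy <- xy + stats::runif(length(xy), -0.01, 0.01)
    d <- geosphere::distm(xy) / 1000
  }
  pc <- if (is.null(truncation)) {
    vegan::pcnm(stats::as.dist(d))
  } else {
    vegan::pcnm(stats::as.dist(d), threshold = truncation)
  }
  v <- pc$vectors
  rownames(v) <- coords$population
  list(vectors = v, values = pc$values[pc$values > 0],
       truncation = pc$threshold)
}

# internal: data.frame-safe wrapper around a predictor matrix
.as_pred_df <- function(X, prefix = "x") {
  X <- as.data.frame(X)
  if (is.null(colnames(X)) || any(colnames(X) == "")) {
    colnames(X) <- paste0(prefix, seq_len(ncol(X)))
  }
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  X
}

#' Forward selection of constraining variables
#'
#' Greedy addition maximizing added adjusted R^2 with the double stopping
#' rule: the added variable must pass a permutation test at `alpha` and the
#' cumulative adjusted R^2 may not exceed the global model's
#' (vegan::ordiR2step).
#'
#' @param Y response matrix (centered population allele frequencies).
#' @param X candidate predictor matrix or data.frame.
#' @param alpha per-variable permutation significance level.
#' @param n_perm permutations per step.
#' @return character vector of selected column names (possibly empty).
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 999) {
  X <- .as_pred_df(X)
  # ordiR2step refits models via update(); bind rda in the formula
  # environment so the refits resolve without vegan on the search path
  rda <- vegan::rda
  m0 <- rda(Y ~ 1, data = X)
  m1 <- suppressWarnings(rda(Y ~ ., data = X))
  # with more candidates than populations the global model is saturated
  # and its adjusted R^2 is meaningless; keep only the permutation rule
  r2scope <- ncol(X) < nrow(as.matrix(Y)) - 1
  sel <- tryCatch(
    suppressWarnings(
      vegan::ordiR2step(m0, scope = stats::formula(m1), Pin = alpha,
                        R2scope = r2scope, trace = FALSE,
                        permutations = permute::how(nperm = n_perm),
                        direction = "forward")),
    error = function(e) m0
  )
  lbl <- attr(stats::terms(sel), "term.labels")
  if (is.null(lbl)) character() else lbl
}

#' Redundancy analysis of population allele frequencies
#'
#' Multivariate OLS of Y on X followed by a PCA of the fitted values
#' (vegan::rda). Reports canonical eigenvalues, population scores, SNP
#' loadings, variable-axis (biplot) correlations, R^2, Ezekiel-adjusted
#' R^2, and per-axis permutation p-values (forward axis test). Aliased
#' predictors are dropped by the underlying fit with a warning from vegan.
#'
#' @param Y populations x SNP (centered) frequency matrix.
#' @param X constraining matrix/data.frame.
#' @param Z optional conditioning matrix (partial RDA: Y and X are
#'   residualized on Z first).
#' @param n_perm permutations for the axis tests (0 skips them).
#' @param scale_snps scale SNP columns to unit variance (default keeps
#'   frequency units).
#' @return an `rda_result` list: `eig`, `site_scores`, `snp_loadings`,
#'   `biplot`, `r2`, `adj_r2`, `axis_p`, `rank`, `fit`.
#' @export
rda_gea <- function(Y, X, Z = NULL, n_perm = 999, scale_snps = FALSE) {
  Y <- as.matrix(Y)
  X <- .as_pred_df(X, "env")
  dat <- X
  rhs <- paste(colnames(X), collapse = " + ")
  if (!is.null(Z)) {
    Z <- .as_pred_df(Z, "cond")
    colnames(Z) <- paste0("cond_", colnames(Z))  # no clashes with X
    dat <- cbind(X, Z)
    rhs <- paste(rhs, "+ Condition(",
                 paste(colnames(Z), collapse = " + "), ")")
  }
  fml <- stats::as.formula(paste("Y ~", rhs))
  fit <- vegan::rda(fml, data = dat, scale = scale_snps)
  r2a <- vegan::RsquareAdj(fit)
  axis_p <- NULL
  if (n_perm > 0) {
    an <- tryCatch(
      stats::anova(fit, by = "axis",
                   permutations = permute::how(nperm = n_perm)),
      error = function(e) NULL)
    if (!is.null(an)) axis_p <- an[["Pr(>F)"]][seq_along(fit$CCA$eig)]
  }
  structure(list(
    eig = fit$CCA$eig,
    site_scores = fit$CCA$u,
    snp_loadings = fit$CCA$v,
    biplot = fit$CCA$biplot,
    r2 = r2a$r.squared,
    adj_r2 = r2a$adj.r.squared,
    axis_p = axis_p,
    rank = fit$CCA$rank,
    fit = fit
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> %d constrained axes, R2 = %.3f (adj %.3f)\n",
              x$rank, x$r2, x$adj_r2))
  if (!is.null(x$axis_p)) {
    cat("  axis p:", paste(signif(x$axis_p, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Partial RDA
#'
#' [rda_gea()] with a conditioning matrix: Y and X are residualized on Z,
#' and the reported fractions are on the adjusted-R^2 scale of the
#' conditioned model.
#'
#' @inheritParams rda_gea
#' @return an `rda_result`.
#' @export
partial_rda <- function(Y, X, Z, n_perm = 999, scale_snps = FALSE) {
  rda_gea(Y, X, Z = Z, n_perm = n_perm, scale_snps = scale_snps)
}

#' Variance partitioning between environment and geography
#'
#' Adjusted-R^2 inclusion-exclusion over the models \{X_env\}, \{X_geo\}
#' and their union: env-only = adj(full) - adj(geo), geo-only =
#' adj(full) - adj(env), shared = adj(env) + adj(geo) - adj(full).
#' Slightly negative fractions (an adjusted-R^2 artifact) are reported as
#' computed.
#'
#' @param Y centered population allele-frequency matrix.
#' @param X_env,X_geo forward-selected predictor matrices.
#' @return list: env_only, geo_only, shared, unexplained, full_adj_r2,
#'   env_marginal, geo_marginal.
#' @export
variance_partition <- function(Y, X_env, X_geo) {
  X_env <- .as_pred_df(X_env, "env")
  X_geo <- .as_pred_df(X_geo, "geo")
  colnames(X_env) <- paste0("env_", colnames(X_env))
  colnames(X_geo) <- paste0("geo_", colnames(X_geo))
  adj <- function(X) {
    vegan::RsquareAdj(vegan::rda(Y ~ ., data = X))$adj.r.squared
  }
  a_env <- adj(X_env)
  a_geo <- adj(X_geo)
  a_full <- adj(cbind(X_env, X_geo))
  list(
    env_only = a_full - a_geo,
    geo_only = a_full - a_env,
    shared = a_env + a_geo - a_full,
    unexplained = 1 - a_full,
    full_adj_r2 = a_full,
    env_marginal = a_env,
    geo_marginal = a_geo
  )
}

#' RDA-axis outlier SNPs
#'
#' `mahalanobis`: squared Mahalanobis distance of SNP loadings across the
#' retained axes, rescaled by a genomic inflation factor (median distance /
#' chi-square median at df = `n_axes`), chi-square p-values and
#' Benjamini-Hochberg q-values. `sd3`: flags any |loading| > 3 SD on a
#' retained axis (no q-values).
#'
#' @param result an `rda_result`.
#' @param n_axes number of leading (significant) axes to scan (>= 1).
#' @param method `"mahalanobis"` or `"sd3"`.
#' @param q_threshold FDR level used for the `outlier` flag.
#' @return data.frame: site, statistic, p (mahalanobis only), q, outlier.
#' @export
rda_outliers <- function(result, n_axes, method = c("mahalanobis", "sd3"),
                         q_threshold = 0.05) {
  method <- match.arg(method)
  if (n_axes < 1) stop("n_axes must be >= 1", call. = FALSE)
  L <- result$snp_loadings[, seq_len(n_axes), drop = FALSE]
  site <- rownames(L) %||% as.character(seq_len(nrow(L)))
  if (method == "mahalanobis") {
    d2 <- stats::mahalanobis(L, colMeans(L), stats::cov(L))
    gif <- stats::median(d2) / stats::qchisq(0.5, df = n_axes)
    p <- stats::pchisq(d2 / gif, df = n_axes, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(site = site, statistic = d2, p = p, q = q,
               outlier = q < q_threshold, stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    Zs <- scale(L)
    flag <- apply(abs(Zs) > 3, 1, any)
    data.frame(site = site, statistic = apply(abs(Zs), 1, max),
               p = NA_real_, q = NA_real_, outlier = flag,
               stringsAsFactors = FALSE, row.names = NULL)
  }
}
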