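# Genotype-phenotype association: group-wise quantile normalization,
# centered kinship, exact kinship-corrected LMM scan (eigendecomposition +
# per-SNP 1-D REML), and a permutation genome-wide threshold.

#' Group-wise quantile normalization of damage scores
#'
#' Within the experimental design (replication x freezing time point by
#' default), each group's values are mapped onto the common distribution --
#' the mean of the sorted group vectors, interpolated to each group's size
#' -- so phenotypes are comparable across replicates and time points. Ties
#' within a group receive the average of their mapped values; ranks within
#' each group are preserved.
#'
#' @param scores numeric vector.
#' @param groups factor/vector of group labels (e.g.
#'   `interaction(rep, ddi)`).
#' @return normalized numeric vector, same order as `scores`.
#' @export
quantile_normalize <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  idx <- split(seq_along(scores), groups)
  sizes <- lengths(idx)
  if (any(sizes == 1)) {
    warning("group(s) of size 1 passed through unchanged")
  }
  # reference distribution: mean of sorted group vectors on a common grid
  grid_n <- max(sizes)
  probs <- seq(0, 1, length.out = grid_n)
  qs <- vapply(idx, function(i) {
    stats::quantile(scores[i], probs, names = FALSE, type = 7)
  }, numeric(grid_n))
  ref <- rowMeans(qs)
  out <- scores
  for (i in idx) {
    if (length(i) == 1) next
    target <- stats::quantile(ref, seq(0, 1, length.out = length(i)),
                              names = FALSE, type = 7)
    r <- rank(scores[i], ties.method = "average")
    # average ranks may be fractional under ties: interpolate the target
    out[i] <- stats::approx(seq_along(i), target, xout = r)$y
  }
  out
}

#' Centered-genotype kinship matrix
#'
#' K = X_c X_c' / p with X_c the column-centered dosage matrix over p
#' polymorphic sites (missing calls imputed to the site mean). Symmetric
#' positive semi-definite by construction.
#'
#' @param g a [geno_matrix()] or a plain dosage matrix.
#' @return n x n kinship matrix.
#' @export
kinship_centered <- function(g) {
  X <- if (inherits(g, "geno_matrix")) g$calls else as.matrix(g)
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  keep <- apply(X, 2, stats::sd) > 0
  if (!any(keep)) stop("no polymorphic sites", call. = FALSE)
  Xc <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  tcrossprod(Xc) / sum(keep)
}

# internal: REML profile log-likelihood machinery on rotated data.
# K = U D U'; for fixed lambda = sigma2_g / sigma2_e the GLS weights are
# 1 / (lambda * d + 1) in the eigenbasis.
.lmm_reml_ll <- function(log_lambda, yr, Wr, d) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  WtW <- crossprod(Wr * w, Wr)
  Wty <- crossprod(Wr * w, yr)
  bh <- solve(WtW, Wty)
  r <- yr - Wr %*% bh
  rss <- sum(w * r^2)
  n <- length(yr); q <- ncol(Wr)
  -0.5 * ((n - q) * log(rss) - sum(log(w)) +
            determinant(WtW, logarithm = TRUE)$modulus)
}

# internal: Wald test of the last column of Wr at fixed lambda
.lmm_wald <- function(lambda, yr, Wr, d) {
  w <- 1 / (lambda * d + 1)
  WtW <- crossprod(Wr * w, Wr)
  Wty <- crossprod(Wr * w, yr)
  bh <- solve(WtW, Wty)
  r <- yr - Wr %*% bh
  n <- length(yr); q <- ncol(Wr)
  s2 <- sum(w * r^2) / (n - q)
  vb <- solve(WtW)[q, q] * s2
  tstat <- bh[q] / sqrt(vb)
  c(beta = bh[q], se = sqrt(vb), stat = tstat,
    p = 2 * stats::pt(abs(tstat), df = n - q, lower.tail = FALSE))
}

#' Kinship-corrected LMM association scan
#'
#' y = W alpha + x beta + g + e with g ~ N(0, sigma2_g K). K is
#' eigendecomposed once; per SNP the variance ratio lambda =
#' sigma2_g / sigma2_e is optimized by 1-D bounded REML search on the
#' rotated data and beta is tested by a Wald t-test; q-values are
#' Benjamini-Hochberg. With K = I the model collapses to OLS exactly.
#'
#' @param y normalized phenotype vector.
#' @param G dosage matrix (individuals x SNPs) or [geno_matrix()]; missing
#'   calls are mean-imputed.
#' @param K kinship matrix from [kinship_centered()].
#' @param covariates matrix of covariates (default intercept only).
#' @return an `assoc_result` list: `snps` (data.frame site, beta, se,
#'   stat, p, q; monomorphic SNPs carry NA and a flag), `null_lambda`
#'   (REML variance ratio of the no-SNP model), `eigen` (reusable
#'   eigendecomposition).
#' @export
lmm_scan <- function(y, G, K, covariates = NULL) {
  X <- if (inherits(G, "geno_matrix")) G$calls else as.matrix(G)
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  n <- length(y)
  W <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  yr <- as.numeric(Ut %*% y)
  Wr <- Ut %*% W
  Xr <- Ut %*% X
  null_opt <- stats::optimize(.lmm_reml_ll, c(-12, 12), yr = yr, Wr = Wr,
                              d = d, maximum = TRUE)
  null_lambda <- exp(null_opt$maximum)
  p_snp <- ncol(X)
  res <- matrix(NA_real_, p_snp, 4,
                dimnames = list(NULL, c("beta", "se", "stat", "p")))
  mono <- apply(X, 2, stats::sd) == 0
  for (j in which(!mono)) {
    Wj <- cbind(Wr, Xr[, j])
    opt <- stats::optimize(.lmm_reml_ll, c(-12, 12), yr = yr, Wr = Wj,
                           d = d, maximum = TRUE)
    res[j, ] <- .lmm_wald(exp(opt$maximum), yr, Wj, d)
  }
  snps <- data.frame(
    site = colnames(X) %||% as.character(seq_len(p_snp)),
    beta = res[, "beta"], se = res[, "se"], stat = res[, "stat"],
    p = res[, "p"], q = NA_real_, monomorphic = mono,
    stringsAsFactors = FALSE
  )
  snps$q[!mono] <- stats::p.adjust(snps$p[!mono], method = "BH")
  structure(list(snps = snps, null_lambda = null_lambda,
                 eigen = list(values = d, Ut = Ut, Wr = Wr, Xr = Xr,
                              mono = mono)),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  tested <- sum(!x$snps$monomorphic)
  cat(sprintf("<assoc_result> %d SNPs tested, min p = %.3g, %d at q < 0.05\n",
              tested, min(x$snps$p, na.rm = TRUE),
              sum(x$snps$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Permutation genome-wide significance threshold
#'
#' Phenotypes are shuffled `n_perm` times; for each shuffle the minimum
#' p-value over all SNPs is recorded (holding the null model's REML
#' variance ratio fixed across SNPs, so each permutation scan is a single
#' weighted regression sweep); the threshold is the 5th percentile of the
#' min-p distribution.
#'
#' @param y phenotype vector.
#' @param G dosage matrix or [geno_matrix()].
#' @param K kinship matrix.
#' @param n_perm number of shuffles (default 1000; < 20 warns).
#' @param seed RNG seed.
#' @param scan an optional precomputed [lmm_scan()] result to reuse the
#'   eigendecomposition.
#' @return list: `threshold` (5th percentile of min p), `min_p` (the
#'   permutation distribution).
#' @export
perm_threshold <- function(y, G, K, n_perm = 1000, seed = 1, scan = NULL) {
  if (n_perm < 20) warning("n_perm < 20: threshold will be unstable")
  if (is.null(scan)) scan <- lmm_scan(y, G, K)
  eg <- scan$eigen
  set.seed(seed)
  lambda <- scan$null_lambda
  w <- 1 / (lambda * eg$values + 1)
  Xr <- eg$Xr[, !eg$mono, drop = FALSE]
  Wr <- eg$Wr
  n <- length(y)
  q0 <- ncol(Wr)
  sw <- sqrt(w)
  Ws <- Wr * sw
  Xs <- Xr * sw
  # project out covariates once in the whitened basis
  qrW <- qr(Ws)
  Xp <- Xs - qr.fitted(qrW, Xs)
  xnorm2 <- colSums(Xp^2)
  df <- n - q0 - 1
  min_p <- vapply(seq_len(n_perm), function(b) {
    yp <- (eg$Ut %*% sample(y)) * sw
    ypp <- yp - qr.fitted(qrW, yp)
    bj <- crossprod(Xp, ypp) / xnorm2
    rss <- sum(ypp^2) - bj^2 * xnorm2
    tstat <- bj * sqrt(xnorm2) / sqrt(rss / df)
    2 * stats::pt(max(abs(tstat)), df = df, lower.tail = FALSE)
  }, numeric(1))
  list(threshold = unname(stats::quantile(min_p, 0.05)), min_p = min_p)
}
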