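# Diversity and differentiation statistics: observed/expected
# heterozygosity, permutation F_IS, nucleotide diversity by site class,
# Weir-Cockerham F_ST (global, pairwise, per-locus components),
# isolation-by-distance regression, and genotype PCA.

# internal: per-site allele freq / het summaries for one set of rows
.site_summary <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  het <- ifelse(n_obs > 0, colSums(calls == 1L, na.rm = TRUE) / n_obs,
                NA_real_)
  list(n = n_obs, p = p, het = het)
}

#' Observed and expected heterozygosity per population
#'
#' Per site, H_o is the heterozygote fraction among non-missing calls and
#' H_e the unbiased expected heterozygosity 2*p*q * 2n/(2n-1). Values are
#' averaged over sites polymorphic in the full dataset (so every population
#' shares a denominator; set `polymorphic_within = TRUE` to average over
#' sites polymorphic within each population instead). Sites with fewer than
#' two genotyped individuals in a population are skipped for that
#' population.
#'
#' @param g a [geno_matrix()].
#' @param polymorphic_within average over per-population polymorphic sites
#'   instead of dataset-wide polymorphic sites.
#' @return data.frame with rows per population plus an `overall` row:
#'   population, n (median genotyped individuals), ho, he.
#' @export
het_stats <- function(g, polymorphic_within = FALSE) {
  calls <- g$calls
  all_s <- .site_summary(calls)
  poly_all <- !is.na(all_s$p) & all_s$p > 0 & all_s$p < 1
  pops <- split(seq_len(nrow(calls)), g$samples$population)
  row_for <- function(rows, label) {
    s <- .site_summary(calls[rows, , drop = FALSE])
    use <- if (polymorphic_within) {
      !is.na(s$p) & s$p > 0 & s$p < 1
    } else poly_all
    use <- use & s$n >= 2
    he <- 2 * s$p[use] * (1 - s$p[use]) *
      (2 * s$n[use]) / (2 * s$n[use] - 1)
    data.frame(population = label, n = length(rows),
               ho = mean(s$het[use]), he = mean(he),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(names(pops),
                               function(p) row_for(pops[[p]], p)))
  rbind(res, row_for(seq_len(nrow(calls)), "overall"))
}

# internal: number of heterozygous pairs when n_alt alt alleles among
# 2n gene copies are paired uniformly at random into n individuals.
# The permutation distribution conditional on the allele count is exact:
# P(h) proportional to 2^h * n! / (n_AA! h! n_rr!) with n_AA = (n_alt-h)/2,
# so draws are sampled from it directly instead of physically permuting.
.perm_het_counts <- function(n_ind, n_alt, n_perm) {
  support <- seq.int(n_alt %% 2L, min(n_alt, 2L * n_ind - n_alt), by = 2L)
  lp <- support * log(2) + lfactorial(n_ind) -
    lfactorial((n_alt - support) / 2) - lfactorial(support) -
    lfactorial(n_ind - (n_alt + support) / 2)
  p <- exp(lp - max(lp))
  if (length(support) == 1L) return(rep(support, n_perm))
  sample(support, n_perm, replace = TRUE, prob = p)
}

#' Permutation test of the within-population fixation index
#'
#' F_IS = 1 - mean(H_o) / mean(H_e) over polymorphic sites
#' (ratio-of-averages; `average_of_ratios = TRUE` averages per-site
#' 1 - H_o/H_e instead). The null distribution permutes gene copies among
#' individuals within the population at each locus independently (expected
#' heterozygosity is invariant under such shuffles, so only H_o is
#' recomputed); the two-sided p-value is
#' (#\{|F_perm| >= |F_obs|\} + 1) / (n_perm + 1).
#'
#' @param g a [geno_matrix()].
#' @param n_perm number of permutations (default 1023).
#' @param average_of_ratios alternative F_IS convention.
#' @return data.frame per population: population, fis, p_value; fis is NA
#'   when no site is polymorphic in the population.
#' @export
fis_permutation <- function(g, n_perm = 1023, average_of_ratios = FALSE) {
  stopifnot(n_perm >= 1)
  pops <- split(seq_len(nrow(g$calls)), g$samples$population)
  fis_from <- function(ho, he) {
    if (average_of_ratios) mean(1 - ho / he) else 1 - mean(ho) / mean(he)
  }
  res <- lapply(names(pops), function(pn) {
    calls <- g$calls[pops[[pn]], , drop = FALSE]
    s <- .site_summary(calls)
    use <- which(!is.na(s$p) & s$p > 0 & s$p < 1 & s$n >= 2)
    if (!length(use)) {
      return(data.frame(population = pn, fis = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    he <- 2 * s$p[use] * (1 - s$p[use]) * (2 * s$n[use]) / (2 * s$n[use] - 1)
    f_obs <- fis_from(s$het[use], he)
    # permuted H_o per locus: random re-pairing of the observed gene
    # copies; expected heterozygosity is invariant under the shuffle
    acc <- numeric(n_perm)
    for (j in seq_along(use)) {
      l <- use[j]
      n_i <- s$n[l]
      n_alt <- round(2 * n_i * s$p[l])
      draws <- .perm_het_counts(n_i, n_alt, n_perm) / n_i
      acc <- acc + if (average_of_ratios) draws / he[j] else draws
    }
    f_perm <- 1 - (acc / length(use)) / if (average_of_ratios) 1 else
      mean(he)
    p <- (sum(abs(f_perm) >= abs(f_obs)) + 1) / (n_perm + 1)
    data.frame(population = pn, fis = f_obs, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Nucleotide diversity overall and by degeneracy class
#'
#' pi per class = sum over variant sites in the class of the unbiased
#' per-site heterozygosity [2n/(2n-1)] * 2*p*q, divided by the total number
#' of callable sites of that class (monomorphic sites included in the
#' denominator but absent from a variants-only VCF, hence supplied as
#' `total_sites`).
#'
#' @param g a [geno_matrix()].
#' @param site_classes character vector along sites with values in
#'   `c("zero_fold", "four_fold", "other")`, or NULL for `pi_all` only.
#' @param total_sites named list/vector of callable site totals; needs
#'   `all` and, when `site_classes` is given, `zero_fold` and `four_fold`.
#' @return named numeric vector `pi_all` (and `pi_0`, `pi_4`).
#' @export
nucleotide_diversity <- function(g, site_classes = NULL, total_sites) {
  if (missing(total_sites) || is.null(total_sites$all)) {
    stop("total callable site counts are required to normalize pi",
         call. = FALSE)
  }
  s <- .site_summary(g$calls)
  contrib <- ifelse(
    !is.na(s$p) & s$n >= 2,
    2 * s$p * (1 - s$p) * (2 * s$n) / (2 * s$n - 1), 0)
  out <- c(pi_all = sum(contrib) / total_sites$all)
  if (!is.null(site_classes)) {
    stopifnot(length(site_classes) == ncol(g$calls))
    for (cl in c("zero_fold", "four_fold")) {
      if (is.null(total_sites[[cl]])) {
        stop(sprintf("total_sites lacks the '%s' class total", cl),
             call. = FALSE)
      }
    }
    out["pi_0"] <- sum(contrib[site_classes == "zero_fold"]) /
      total_sites$zero_fold
    out["pi_4"] <- sum(contrib[site_classes == "four_fold"]) /
      total_sites$four_fold
  }
  out
}

# internal: Weir-Cockerham (1984) per-locus a/b/c variance components for a
# set of populations given per-pop per-site (n, p, het) matrices.
# All arguments are pops x sites matrices. Returns list(a, b, c) matrices.
.wc_components <- function(n, p, h) {
  use <- n >= 1
  n[!use] <- NA
  r_l <- colSums(use)                       # populations with data per locus
  n_tot <- colSums(n, na.rm = TRUE)
  nbar <- n_tot / r_l
  nc <- (n_tot - colSums(n^2, na.rm = TRUE) / n_tot) / (r_l - 1)
  pbar <- colSums(n * p, na.rm = TRUE) / n_tot
  s2 <- colSums(n * sweep(p, 2, pbar)^2, na.rm = TRUE) / ((r_l - 1) * nbar)
  hbar <- colSums(n * h, na.rm = TRUE) / n_tot
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r_l - 1) / r_l * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r_l < 2 | !is.finite(nc) | nc <= 0 | nbar <= 1
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  list(a = a, b = b, c = cc)
}

# internal: per-pop per-site summary matrices for WC
.pop_site_matrices <- function(g) {
  pops <- split(seq_len(nrow(g$calls)), g$samples$population)
  k <- length(pops); L <- ncol(g$calls)
  n <- p <- h <- matrix(NA_real_, k, L,
                        dimnames = list(names(pops), colnames(g$calls)))
  for (i in seq_along(pops)) {
    s <- .site_summary(g$calls[pops[[i]], , drop = FALSE])
    n[i, ] <- s$n; p[i, ] <- s$p; h[i, ] <- s$het
  }
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham F_ST
#'
#' Per-locus a/b/c variance components (Weir & Cockerham 1984) with the
#' multi-locus ratio-of-sums estimator, globally and for every population
#' pair. Negative estimates are reported as computed. Pairwise significance
#' comes from permuting individuals between the two populations.
#'
#' @param g a [geno_matrix()] with >= 2 populations.
#' @param pairwise compute the pairwise matrix (and permutation p-values
#'   when `n_perm > 0`).
#' @param n_perm permutations per pair (0 skips the test).
#' @return list with `global` (multi-locus F_ST), `per_locus` (data.frame
#'   site, a, b, c, fst), and when requested `pairwise` and `pairwise_p`
#'   (symmetric matrices, zero/NA diagonal).
#' @export
wc_fst <- function(g, pairwise = TRUE, n_perm = 0) {
  m <- .pop_site_matrices(g)
  k <- nrow(m$n)
  if (k < 2) stop("need at least two populations", call. = FALSE)
  comp <- .wc_components(m$n, m$p, m$h)
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  global <- sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  per_locus <- data.frame(
    site = colnames(g$calls) %||% seq_len(ncol(g$calls)),
    a = comp$a, b = comp$b, c = comp$c,
    fst = comp$a / (comp$a + comp$b + comp$c),
    stringsAsFactors = FALSE
  )
  out <- list(global = global, per_locus = per_locus)
  if (pairwise) {
    pops <- rownames(m$n)
    fmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    diag(fmat) <- 0
    pair_fst <- function(ni, pi_, hi) {
      cmp <- .wc_components(ni, pi_, hi)
      okp <- is.finite(cmp$a) & is.finite(cmp$b) & is.finite(cmp$c)
      if (!any(okp)) return(NA_real_)
      sum(cmp$a[okp]) / sum(cmp$a[okp] + cmp$b[okp] + cmp$c[okp])
    }
    idx_by_pop <- split(seq_len(nrow(g$calls)), g$samples$population)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        fij <- pair_fst(m$n[c(i, j), , drop = FALSE],
                        m$p[c(i, j), , drop = FALSE],
                        m$h[c(i, j), , drop = FALSE])
        fmat[i, j] <- fmat[j, i] <- fij
        if (n_perm > 0 && is.finite(fij)) {
          rows <- c(idx_by_pop[[pops[i]]], idx_by_pop[[pops[j]]])
          n_i <- length(idx_by_pop[[pops[i]]])
          calls_ij <- g$calls[rows, , drop = FALSE]
          exceed <- 0L
          for (b in seq_len(n_perm)) {
            sh <- sample(length(rows))
            grp <- rep("b", length(rows)); grp[sh[seq_len(n_i)]] <- "a"
            gi <- .site_summary(calls_ij[grp == "a", , drop = FALSE])
            gj <- .site_summary(calls_ij[grp == "b", , drop = FALSE])
            fp <- pair_fst(rbind(gi$n, gj$n), rbind(gi$p, gj$p),
                           rbind(gi$het, gj$het))
            if (is.finite(fp) && fp >= fij) exceed <- exceed + 1L
          }
          pmat[i, j] <- pmat[j, i] <- (exceed + 1) / (n_perm + 1)
        }
      }
    }
    out$pairwise <- fmat
    if (n_perm > 0) out$pairwise_p <- pmat
  }
  out
}

#' Isolation-by-distance regression
#'
#' OLS of off-diagonal pairwise F_ST on a pairwise distance, with
#' significance from permuting population labels (Mantel-style, respecting
#' the non-independence of pairs).
#'
#' @param fst_matrix symmetric pairwise F_ST matrix.
#' @param dist_matrix symmetric pairwise distance matrix (geographic or
#'   environmental), conformable with `fst_matrix`.
#' @param n_perm label permutations (default 999).
#' @return list: slope, intercept, r2, adj_r2, p_value.
#' @export
ibd_regression <- function(fst_matrix, dist_matrix, n_perm = 999) {
  stopifnot(all(dim(fst_matrix) == dim(dist_matrix)))
  k <- nrow(fst_matrix)
  lower <- lower.tri(fst_matrix)
  y <- fst_matrix[lower]
  x <- dist_matrix[lower]
  if (stats::sd(x) == 0) stop("constant distances: slope undefined",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  stat_perm <- vapply(seq_len(n_perm), function(b) {
    o <- sample(k)
    xp <- dist_matrix[o, o][lower]
    if (stats::sd(xp) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ xp))[2])
  }, numeric(1))
  p <- (sum(abs(stat_perm) >= abs(slope), na.rm = TRUE) + 1) / (n_perm + 1)
  list(slope = slope, intercept = unname(stats::coef(fit)[1]), r2 = r2,
       adj_r2 = .adj_r2(r2, length(y), 1), p_value = p)
}

#' Genotype PCA
#'
#' Missing calls are imputed to the per-site mean dosage; sites are centered
#' and scaled by sqrt(p*(1-p)); eigendecomposition of the sample covariance
#' of individuals. Zero-variance sites are excluded (count logged as an
#' attribute).
#'
#' @param g a [geno_matrix()].
#' @param n_axes number of axes to return.
#' @return list: scores (individuals x axes), eigenvalues (all),
#'   var_frac (variance fraction per returned axis), n_dropped.
#' @export
genotype_pca <- function(g, n_axes = 10) {
  X <- g$calls
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  p_hat <- mu / 2
  sc <- sqrt(p_hat * (1 - p_hat))
  keep <- sc > 0 & apply(X, 2, stats::sd) > 0
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sc[keep], "/")
  sv <- svd(X, nu = min(n_axes, nrow(X) - 1), nv = 0)
  eig <- sv$d^2 / (nrow(X) - 1)
  n_axes <- min(n_axes, ncol(sv$u))
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- g$samples$id
  list(scores = scores, eigenvalues = eig,
       var_frac = eig[seq_len(n_axes)] / sum(eig),
       n_dropped = sum(!keep))
}
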