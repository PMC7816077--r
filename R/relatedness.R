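#' Screen for close relatives within populations
#'
#' Pairwise kinship within each population from a robust moment estimator on
#' shared-heterozygote and opposite-homozygote counts
#' (KING-robust): phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j)),
#' where counts run over sites genotyped in both individuals. Duplicates
#' give phi ~ 0.5, full sibs ~ 0.25, first cousins ~ 0.0625; the default
#' threshold 0.0442 is the lower bound of the first-cousin band
#' (2^(-9/2)). A prune list is built greedily by repeatedly removing the
#' individual appearing in the most flagged pairs.
#'
#' @param g a [geno_matrix()] with >= 2 individuals in each screened
#'   population.
#' @param threshold kinship at or above which a pair is flagged.
#' @param min_sites pairs with fewer overlapping non-missing sites are
#'   skipped with a warning.
#' @return list with `pairs` (data.frame id1, id2, population, kinship,
#'   n_sites, flagged) and `prune` (character vector of ids to drop).
#' @export
screen_relatedness <- function(g, threshold = 0.0442, min_sites = 50) {
  pops <- split(seq_len(nrow(g$calls)), g$samples$population)
  out <- list()
  skipped <- 0L
  for (pop in names(pops)) {
    idx <- pops[[pop]]
    if (length(idx) < 2) next
    X <- g$calls[idx, , drop = FALSE]
    ids <- g$samples$id[idx]
    for (i in seq_len(length(idx) - 1)) {
      xi <- X[i, ]
      for (j in seq(i + 1, length(idx))) {
        xj <- X[j, ]
        ok <- !is.na(xi) & !is.na(xj)
        n_ok <- sum(ok)
        if (n_ok < min_sites) { skipped <- skipped + 1L; next }
        a <- xi[ok]; b <- xj[ok]
        n_hh <- sum(a == 1L & b == 1L)
        n_opp <- sum((a == 0L & b == 2L) | (a == 2L & b == 0L))
        n_het_i <- sum(a == 1L); n_het_j <- sum(b == 1L)
        denom <- n_het_i + n_het_j
        phi <- if (denom > 0) (n_hh - 2 * n_opp) / denom else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], population = pop,
          kinship = phi, n_sites = n_ok,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d pair(s) skipped (< %d overlapping sites)",
                    skipped, min_sites))
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(), id2 = character(),
               population = character(), kinship = numeric(),
               n_sites = integer())
  pairs$flagged <- !is.na(pairs$kinship) & pairs$kinship >= threshold
  prune <- character()
  flg <- pairs[pairs$flagged, c("id1", "id2")]
  while (nrow(flg) > 0) {
    tab <- sort(table(c(flg$id1, flg$id2)), decreasing = TRUE)
    worst <- names(tab)[1]
    prune <- c(prune, worst)
    flg <- flg[flg$id1 != worst & flg$id2 != worst, , drop = FALSE]
  }
  list(pairs = pairs, prune = prune)
}
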