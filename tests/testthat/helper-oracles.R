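# Independent oracles and fixture builders used across the suite.

# Build a geno_matrix from a plain dosage matrix and population labels.
toy_geno <- function(calls, pops, gq = NULL, dp = NULL) {
  calls <- as.matrix(calls)
  p <- ncol(calls)
  geno_matrix(
    calls,
    sites = data.frame(id = paste0("s", seq_len(p)), chrom = "chr1",
                       pos = seq_len(p) * 100L, ref = "A", alt = "G",
                       biallelic = TRUE, stringsAsFactors = FALSE),
    samples = data.frame(id = paste0("i", seq_len(nrow(calls))),
                         population = pops, stringsAsFactors = FALSE),
    gq = gq, dp = dp
  )
}

# Scalar, loop-based Weir-Cockerham (1984) a/b/c oracle. Arguments:
# a list of per-population dosage vectors for ONE locus. Returns c(a, b, c).
wc_abc_oracle <- function(pop_calls) {
  pop_calls <- lapply(pop_calls, function(x) x[!is.na(x)])
  pop_calls <- pop_calls[lengths(pop_calls) >= 1]
  r <- length(pop_calls)
  if (r < 2) return(c(NA, NA, NA))
  n_i <- sapply(pop_calls, length)
  p_i <- sapply(pop_calls, function(x) sum(x) / (2 * length(x)))
  h_i <- sapply(pop_calls, function(x) mean(x == 1))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(NA, NA, NA))
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  if (nc <= 0) return(c(NA, NA, NA))
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

# Multi-locus ratio-of-sums oracle over a geno_matrix.
wc_fst_oracle <- function(g) {
  pops <- split(seq_len(nrow(g$calls)), g$samples$population)
  abc <- t(vapply(seq_len(ncol(g$calls)), function(l) {
    wc_abc_oracle(lapply(pops, function(i) g$calls[i, l]))
  }, numeric(3)))
  ok <- stats::complete.cases(abc)
  sum(abc[ok, 1]) / sum(abc[ok, ])
}

# Exact Hardy-Weinberg test (conditional on allele counts): two-sided
# p-value summing genotype-configuration probabilities <= the observed one.
hwe_exact_p <- function(n_het, n_ind, n_alt) {
  probs <- sapply(seq(n_alt %% 2, min(n_alt, 2 * n_ind - n_alt), by = 2),
                  function(h) {
                    n_aa <- (n_alt - h) / 2
                    n_rr <- n_ind - n_aa - h
                    exp(h * log(2) + lfactorial(n_ind) - lfactorial(n_aa) -
                          lfactorial(h) - lfactorial(n_rr) +
                          lfactorial(n_alt) + lfactorial(2 * n_ind - n_alt) -
                          lfactorial(2 * n_ind))
                  })
  obs <- probs[match(n_het, seq(n_alt %% 2, min(n_alt, 2 * n_ind - n_alt),
                                by = 2))]
  sum(probs[probs <= obs + 1e-12])
}

# Reorder/subset a geno_matrix by index (wraps the internal helper).
subset_geno_for_test <- function(g, ind, site) {
  qstfst:::subset_geno(g, ind, site)
}

# Minimal VCF writer for hand-constructed fixtures (header + given rows).
write_toy_vcf <- function(rows, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}
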