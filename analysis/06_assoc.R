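#!/usr/bin/env Rscript
# Stage 6 -- association mapping.
#
# Quantile-normalizes damage scores over replication x freezing time
# point, builds the centered kinship matrix, runs the kinship-corrected
# LMM scan with a permutation genome-wide threshold and the BSLMM for
# PVE / GVE_beta / PVE_beta -- on the full population set and on a
# reduced set excluding the three NW populations, mirroring the
# confounding contrast.

suppressMessages(library(qstfst))
datadir <- "results/data"
outdir <- "results"

samples <- read.delim(file.path(datadir, "samples.tsv"))
g <- read_vcf(file.path(datadir, "genotypes_filtered.vcf"),
              pop_map = samples)
damage <- read.delim(file.path(datadir, "damage.tsv"))
i <- match(g$samples$id, damage$seedling)
y <- quantile_normalize(damage$score[i],
                        interaction(damage$rep[i], damage$ddi[i]))

run_set <- function(g, y, label, seed) {
  cat("==", label, "set:", nrow(g$calls), "individuals\n")
  K <- kinship_centered(g)
  scan <- lmm_scan(y, g, K)
  thr <- perm_threshold(y, g, K, n_perm = 1000, seed = seed, scan = scan)
  n_hit <- sum(scan$snps$p <= thr$threshold, na.rm = TRUE)
  cat(sprintf("  LMM: min p %.3g, permutation threshold %.3g, %d hits\n",
              min(scan$snps$p, na.rm = TRUE), thr$threshold, n_hit))
  bs <- bslmm(y, g, K, iters = 20000, burnin = 6000, thin = 10,
              seed = seed + 1)
  e <- bs$estimates
  cat(sprintf("  BSLMM: PVE %.2f [%.2f, %.2f], PVE_beta %.2f, gamma_N %.1f\n",
              e["pve", "mean"], e["pve", "hpdi_lower"],
              e["pve", "hpdi_upper"], e["pve_beta", "mean"],
              e["gamma_n", "mean"]))
  list(scan = scan, threshold = thr$threshold, bslmm = bs, n_hit = n_hit)
}

full <- run_set(g, y, "full", seed = 7)
cat("note: the trait carries a large between-population adaptive shift\n",
    "(latent Q_ST 0.8), which the kinship term absorbs, so PVE here\n",
    "exceeds the within-population marker heritability (0.56) used by\n",
    "the generator; the acceptance suite checks PVE recovery on\n",
    "within-population architectures.\n")

nw <- g$samples$population %in% paste0("pop", 1:3)
g_red <- qstfst:::subset_geno(g, which(!nw), seq_len(ncol(g$calls)))
red <- run_set(g_red, y[!nw], "reduced (no NW)", seed = 9)

write.table(full$scan$snps, file.path(outdir, "assoc_lmm_full.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(red$scan$snps, file.path(outdir, "assoc_lmm_reduced.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
summ <- function(r) list(
  min_p = min(r$scan$snps$p, na.rm = TRUE), threshold = r$threshold,
  n_hits = r$n_hit,
  pve = r$bslmm$estimates["pve", "mean"],
  pve_hpdi = c(r$bslmm$estimates["pve", "hpdi_lower"],
               r$bslmm$estimates["pve", "hpdi_upper"]),
  pve_beta = r$bslmm$estimates["pve_beta", "mean"],
  gamma_n = r$bslmm$estimates["gamma_n", "mean"])
jsonlite::write_json(list(full = summ(full), reduced = summ(red)),
                     file.path(outdir, "assoc_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(outdir, "assoc_summary.json"), "\n")
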