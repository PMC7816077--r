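#!/usr/bin/env Rscript
# Stage 2 -- genotype QC and diversity.
#
# Masks low-quality calls (GQ < 20 or DP < 5), applies the site filters
# (biallelic, polymorphic, missing <= 30%, het <= 70%, MAF >= 5%),
# screens for close relatives (KING-robust kinship >= 0.0442, the
# first-cousin band), and tabulates per-population H_o, H_e and
# permutation-tested F_IS plus nucleotide diversity.

suppressMessages(library(qstfst))
datadir <- "results/data"
outdir <- "results"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

samples <- read.delim(file.path(datadir, "samples.tsv"))
g <- read_vcf(file.path(datadir, "genotypes.vcf"), pop_map = samples)
g <- mask_low_quality(g)
fl <- filter_sites(g)
cat("site filtering:\n")
str(fl$report)
g <- fl$genotypes

rel <- screen_relatedness(g)
cat(sprintf("relatedness screen: %d flagged pairs, %d pruned\n",
            sum(rel$pairs$flagged), length(rel$prune)))
if (length(rel$prune)) {
  keep <- !(g$samples$id %in% rel$prune)
  g <- qstfst:::subset_geno(g, which(keep), seq_len(ncol(g$calls)))
}
write_vcf(g, file.path(datadir, "genotypes_filtered.vcf"))

het <- het_stats(g)
set.seed(2)
fis <- fis_permutation(g, n_perm = 1023)
div <- merge(het, fis, by = "population", all.x = TRUE, sort = FALSE)
# per-site diversity normalized by a nominal callable-site total per
# 350 bp GBS fragment around each SNP
pi_all <- nucleotide_diversity(g, total_sites = list(all = 350 * ncol(g$calls)))
write.table(div, file.path(outdir, "diversity_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("overall H_o %.4f, H_e %.4f, pi_all %.4g\n",
            div$ho[div$population == "overall"],
            div$he[div$population == "overall"], pi_all["pi_all"]))
cat(sprintf("F_IS significant at 0.05 in %d/%d populations\n",
            sum(fis$p_value < 0.05, na.rm = TRUE), nrow(fis)))
cat("wrote", file.path(outdir, "diversity_table.tsv"), "\n")
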