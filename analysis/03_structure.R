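#!/usr/bin/env Rscript
# Stage 3 -- population structure.
#
# Weir-Cockerham F_ST (global and pairwise), isolation-by-distance
# regressions of pairwise F_ST on geographic and environmental distance,
# and a genotype PCA.

suppressMessages(library(qstfst))
datadir <- "results/data"
outdir <- "results"

samples <- read.delim(file.path(datadir, "samples.tsv"))
g <- read_vcf(file.path(datadir, "genotypes_filtered.vcf"),
              pop_map = samples)
coords <- read.delim(file.path(datadir, "coords.tsv"))
envt <- read.delim(file.path(datadir, "environment.tsv"),
                   check.names = FALSE)
envm <- as.matrix(envt[, -1]); rownames(envm) <- envt$population

fst <- wc_fst(g)
write.table(round(fst$pairwise, 6), file.path(outdir, "fst_pairwise.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
cat(sprintf("global F_ST: %.4f; pairwise mean %.4f (sd %.4f)\n",
            fst$global, mean(fst$pairwise[lower.tri(fst$pairwise)]),
            sd(fst$pairwise[lower.tri(fst$pairwise)])))

ord <- match(rownames(fst$pairwise), coords$population)
geo <- geosphere::distm(cbind(coords$longitude, coords$latitude)[ord, ]) / 1000
envd <- env_pca_distance(envm[rownames(fst$pairwise), ])$distance
set.seed(3)
ibd_geo <- ibd_regression(fst$pairwise, geo)
ibd_env <- ibd_regression(fst$pairwise, envd)
cat(sprintf("IBD: geo adj R2 %.3f (p %.3f); env adj R2 %.3f (p %.3f)\n",
            ibd_geo$adj_r2, ibd_geo$p_value, ibd_env$adj_r2,
            ibd_env$p_value))

pca <- genotype_pca(g, n_axes = 4)
cat(sprintf("PC1+PC2 explain %.2f%% of the genetic covariances\n",
            100 * sum(pca$var_frac[1:2])))
jsonlite::write_json(
  list(global_fst = fst$global, ibd_geo = ibd_geo, ibd_env = ibd_env,
       pc_var_frac = pca$var_frac),
  file.path(outdir, "structure.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote", file.path(outdir, "structure.json"), "\n")
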