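#!/usr/bin/env Rscript
# Stage 5 -- genotype-environment association.
#
# Builds PCNM spatial predictors from the population coordinates,
# forward-selects climate variables and PCNM axes separately, runs the
# full and partial RDA models on population allele frequencies,
# partitions the explained variance into environment-only, geography-only
# and confounded fractions, and scans the significant axes for outlier
# SNPs.

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

Y <- pop_allele_freqs(g)
envm <- envm[rownames(Y), ]
coords <- coords[match(rownames(Y), coords$population), ]

pc <- pcnm_axes(coords)
cat(sprintf("PCNM: %d positive axes (truncation %.0f km)\n",
            ncol(pc$vectors), pc$truncation))

set.seed(6)
sel_env <- forward_select(Y, envm, n_perm = 499)
sel_geo <- forward_select(Y, pc$vectors, n_perm = 499)
cat("selected climate variables:", paste(sel_env, collapse = ", "), "\n")
cat("selected PCNM axes:", paste(sel_geo, collapse = ", "), "\n")
if (!length(sel_env)) sel_env <- colnames(envm)[1]
if (!length(sel_geo)) sel_geo <- colnames(pc$vectors)[1]

Xe <- envm[, sel_env, drop = FALSE]
Xg <- pc$vectors[, sel_geo, drop = FALSE]
vp <- variance_partition(Y, Xe, Xg)
cat(sprintf(
  "variance partition (adj R2): full %.3f = env-only %.3f + geo-only %.3f + confounded %.3f\n",
  vp$full_adj_r2, vp$env_only, vp$geo_only, vp$shared))

r_env <- rda_gea(Y, Xe, n_perm = 999)
print(r_env)
n_sig <- max(1, sum(r_env$axis_p <= 0.05, na.rm = TRUE))
out <- rda_outliers(r_env, n_axes = min(n_sig, r_env$rank))
cat(sprintf("outlier scan on %d axes: %d SNPs at q < 0.05\n",
            min(n_sig, r_env$rank), sum(out$outlier)))

# conditioning on geography: does the environmental signal survive?
r_part <- partial_rda(Y, Xe, Z = Xg, n_perm = 999)
cat(sprintf("partial (env | geo) adj R2: %.3f, first-axis p = %s\n",
            r_part$adj_r2, format(r_part$axis_p[1])))
if (r_part$rank >= 1 && !is.na(r_part$axis_p[1]) &&
    r_part$axis_p[1] <= 0.05) {
  outp <- rda_outliers(r_part, n_axes = 1)
  cat(sprintf("partial-model outliers: %d\n", sum(outp$outlier)))
} else {
  cat("no significant axis once geography is conditioned out\n")
}

write.table(out[out$outlier, ], file.path(outdir, "rda_outliers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(selected_env = sel_env, selected_geo = sel_geo, partition = vp,
       env_rda_adj_r2 = r_env$adj_r2, env_axis_p = r_env$axis_p,
       n_outliers = sum(out$outlier)),
  file.path(outdir, "gea_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote", file.path(outdir, "gea_summary.json"), "\n")
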