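#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study system.
#
# 24 populations (~31 seedlings each) on a jittered grid spanning
# Fennoscandia into western Russia; ~10 925 biallelic SNPs at target
# F_ST 0.004 plus 10 strongly differentiated loci confined to the three
# "NW" marginal populations; 68 climate variables collinear with
# geography; a polygenic frost-damage trait with marker heritability
# 0.56 and latent Q_ST 0.8, scored 0-6 at 10 freezing time points.
# Everything downstream reads the plain-text files written here.

suppressMessages(library(qstfst))
seed <- 1
outdir <- "results/data"

cfg <- sim_config(seed = seed)
cat("simulating genotypes:", cfg$n_pops, "pops x", cfg$n_per_pop,
    "ind x", cfg$n_snps, "SNPs (target F_ST", cfg$target_fst, ")\n")
gsim <- simulate_genotypes(cfg)
env <- simulate_environment(cfg)
dmg <- simulate_damage(cfg, gsim$genotypes, gsim$truth)

write_dataset(list(genotypes = gsim$genotypes, env = env$env,
                   coords = env$coords, damage = dmg$damage,
                   truth = dmg$truth), outdir)

cat(sprintf("true latent Q_ST %.3f (sigma2_B %.3f, sigma2_W %.3f), h2 %.2f\n",
            dmg$truth$true_qst, dmg$truth$true_sigmaB2,
            dmg$truth$true_sigmaW2, dmg$truth$true_h2))
cat(sprintf("outlier loci: %s (pops %s)\n",
            paste(dmg$truth$outlier_ids, collapse = ","),
            paste(cfg$outlier_pops, collapse = ",")))
cat("wrote", outdir, "\n")
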