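---
title: "Methods: comparing phenotypic and genomic differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing phenotypic and genomic differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Boreal conifers such as Scots pine combine near-panmictic genomes
(global F_ST of a few tenths of a percent) with strongly locally adapted
phenology: seedling autumn frost tolerance follows a steep latitudinal
cline. The canonical way to demonstrate divergent selection on such a
trait is the Q_ST–F_ST contrast: if the among-population share of
additive genetic variance for the trait,

Q_ST = σ²_B / (σ²_B + 2 h² σ²_W),

greatly exceeds the genome-wide F_ST, selection — not drift — has
differentiated the populations. This package implements the whole
contrast as one tested workflow: a synthetic genotype–environment–
phenotype generator with known truth, genotype QC from VCF, diversity
and Weir–Cockerham F_ST statistics, a hierarchical Poisson MCMC for the
damage scores that yields posterior Q_ST, redundancy-analysis
genotype–environment association with spatial (PCNM) variance
partitioning, and kinship-corrected association mapping (LMM and
BSLMM). Because real common-garden and GBS data of this scale are not
redistributable, every stage is validated against the generator, where
the estimand is known exactly.

## The damage model

Damage scores are seven ordered classes 0–6 recorded once per seedling
at one of ten freezing time points (days since dormancy initiation,
DDI) within a replication. The observation model is

log λ_i = x_i'β + u_pop(i) + v_pop:rep(i) + e_i,
score_i ~ Poisson(λ_i),

with u ~ N(0, σ²_B), v ~ N(0, σ²_rep) and a seedling-level latent
effect e ~ N(0, σ²_W). A pure Poisson has no free within-population
variance, so σ²_W is realized as this observation-level latent effect
and Q_ST is defined on the log-link scale; per posterior draw,
Q_ST = σ²_B / (σ²_B + 2 h² σ²_W) exactly.

**The score ceiling.** Class 6 means "all needles discolored": the
assay cannot report damage beyond it, so 6 is biologically a
*6-or-worse* category. The default likelihood therefore right-censors
the top class, P(score = 6) = P(Poisson ≥ 6). This is not cosmetic: we
profiled the marginal likelihood of ceiling-capped scores under the
unbounded-Poisson model and found it sharply biased against
overdispersion (with true σ²_W = 0.16 and under 4% of scores at the
cap, the profile peaks near 0.05), which collapses σ²_W and pushes
Q_ST toward 1. With censoring the generator's truth is recovered
essentially unbiasedly across Q_ST ∈ {0.2, 0.5, 0.8} (the acceptance
suite checks ±0.1 with ≥80% HPDI coverage over ten replicates each).
`ceiling = "ignore"` restores the plain-Poisson treatment for
comparison.

**Geography in the fixed effects.** The effect-structure model
(`geography = "fixed"`) includes standardized latitude, longitude,
their interaction and their interactions with DDI, matching how
common-garden damage data are usually analyzed. For Q_ST estimation the
default is `geography = "none"`: a latitude fixed effect is collinear
with any clinal population shift and would absorb exactly the
between-population variance that Q_ST is supposed to measure, driving
σ²_B toward 0. The two uses are deliberately separated.

**Sampler.** Metropolis-within-Gibbs: vectorized random-walk updates
for e, group-wise vectorized updates for u and v, single-site updates
for β (step sizes adapted to ~0.44/0.35 acceptance during burn-in), and
conjugate inverse-gamma draws for the variances, interwoven with a
non-centered rescaling move per latent block (the block and its
variance move together). Without the interweaving the chain sits in the
classic funnel — the variance and its effects shrink together and
split-R̂ on σ²_W exceeds 1.5; with it R̂ ≈ 1.00 at 4000 iterations.
Priors: N(0, 10²) on fixed effects, IG(0.01, 0.01) on variances. HPD
intervals are the shortest intervals containing the stated mass of the
sorted draws. Convergence is reported as single-chain split-R̂ and an
autocorrelation-based effective sample size; R̂ ≥ 1.1 on a variance
triggers a warning but still returns the posterior.

Least-squares population means are posterior means of
exp(β₀ + u_p + σ²_W/2) — response scale with the lognormal correction,
covariates at their standardized reference of zero; a link-scale option
exists. Pairwise Q_ST uses σ²_B(i,j) = (u_i − u_j)²/2 per draw (no
pairwise formula is standard; half the squared difference is the
two-population variance), with h² = 1 unless stated.

## The genomic arm

**Filters.** Calls with GQ < 20 or DP < 5 are masked (strict
inequalities; a call at exactly GQ 20 and DP 5 stays). Site removal is
attributed to the first triggering rule in a fixed order — not
biallelic, monomorphic, missing > 30%, observed heterozygote fraction
> 70%, MAF < 5% (strict, pooled over individuals) — so the report is
deterministic and accounting-complete (removed + survivors = input).

**Relatedness.** The screen uses the KING-robust moment estimator
φ = (N_AaAa − 2 N_AAaa)/(N_Aa(i) + N_Aa(j)) within populations, flagging
pairs at φ ≥ 0.0442 (the 2^(−9/2) lower bound of the first-cousin
band) and pruning greedily by flagged-pair degree. It is
allele-frequency-free, hence robust to the weak structure expected
here.

**Diversity.** Per-site H_e uses the unbiased 2p̂q̂·2n/(2n−1); H_o and
H_e are averaged over sites polymorphic in the full dataset so
populations share a denominator (a per-population-polymorphism switch
exists). F_IS = 1 − mean(H_o)/mean(H_e) (ratio of averages; the other
convention is an option), tested by permuting gene copies among
individuals within the population at each locus independently, 1023
permutations, two-sided p with the +1 correction. H_e is invariant
under that shuffle, so the null draws only re-pair gene copies; the
permutation distribution of the heterozygote count conditional on the
allele count has a closed form and is sampled directly. Nucleotide
diversity divides summed per-site unbiased heterozygosity by supplied
callable-site totals per degeneracy class (monomorphic sites are in the
denominator but absent from a variants-only VCF).

**F_ST.** Weir–Cockerham (1984) a/b/c components per locus with
ratio-of-sums aggregation, globally and per pair; negative estimates
are kept (the near-zero pairwise distribution is roughly symmetric
around its mean, and truncation would bias it); pairwise significance
by permuting individuals between the two populations. An independent
scalar implementation of the same published formulas serves as the
test oracle at 1e-12.

## Genotype–environment association

The response is the population × SNP matrix of alternate-allele
frequencies, column-centered and unscaled (loadings keep
frequency-shift units; a scaling switch exists). Spatial predictors are
PCNM eigenvectors of the great-circle distance matrix truncated at the
longest minimum-spanning-tree edge (larger distances set to 4× the
truncation); the number of positive-eigenvalue axes is emergent (~15
for 24 populations on the default grid). Forward selection follows the
double stopping rule — permutation p ≤ α for the added variable and
cumulative adjusted R² within the global model's — except that when
there are more candidates than populations the global model is
saturated and its adjusted R² is meaningless, so only the permutation
rule applies. Variance partitioning is adjusted-R² inclusion–exclusion
over {env}, {geo}, {env ∪ geo}; slightly negative fractions are
reported as computed. RDA axis significance uses forward permutation
tests of Y rows.

Outlier SNPs on the significant axes: squared Mahalanobis distance of
loadings, rescaled by a genomic inflation factor (median distance over
the χ² median at df = n_axes), χ² p-values, Benjamini–Hochberg
q-values at 5% FDR; a |loading| > 3 SD variant is provided. Null
simulations in the acceptance suite confirm the FDR control.

## Association mapping

Phenotypes are quantile-normalized within replication × time-point
cells (the cell-wise reading of "over replication and freezing time
points"; the reference distribution is the mean of sorted group
vectors interpolated to each cell's size, ties averaged). Kinship is
K = X_c X_c'/p on mean-imputed, column-centered dosages. The LMM scan
eigendecomposes K once and, per SNP, optimizes the REML profile of the
variance ratio by 1-D bounded search on the rotated data, testing the
SNP by a Wald t-test; with K = I this reproduces OLS exactly (an
acceptance oracle at 1e-8 relative). The genome-wide threshold is the
5th percentile of min-p over SNPs across phenotype shuffles, computed
with the null model's variance ratio held fixed so each shuffle is one
whitened regression sweep — the standard approximation for permutation
scans; full per-SNP REML per shuffle would change nothing detectable
at these sizes.

The BSLMM is y = μ + Xβ + u + ε with u ~ N(0, σ²_g K) and
spike-and-slab β. The sampler integrates u out of the variance updates
(the marginal is diagonal in the eigenbasis of K, avoiding the
u–σ²_g funnel), moves the sparse set by add/remove/swap proposals whose
coefficients are drawn from their exact conditionals (acceptance is the
single-coefficient Bayes factor times prior and proposal odds), and
refreshes active coefficients, the slab variance, the inclusion
probability and u from closed-form conditionals. Per draw,
PVE = V(Xβ+u)/(V(Xβ+u)+σ²_e), GVE_β = V(Xβ)/V(Xβ+u), PVE_β = PVE·GVE_β
(sample variances), so PVE_β ≤ PVE holds identically. Point estimates
are reported as posterior means and as the mode of the
density-smoothed marginal, with 95% HPDIs. Default run lengths are
scaled to these problem sizes (2×10⁴ iterations after 6×10³ burn-in at
n ≈ 750, p ≈ 10⁴ in the analysis scripts; 1.2×10⁴ at n = 500,
p = 2000 in the acceptance suite); the production-scale settings
(10⁵ burn-in, 10⁶–10⁷ iterations, thinning 10, ≤500 sparse effects)
remain available through the arguments.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 24 populations × 31
individuals (~750), 10 925 biallelic SNPs under Balding–Nichols
sampling at F = 0.004 with per-site ancestral frequencies U(0.05,
0.95); 10 outlier loci drawn rare (U(0.01, 0.10)) and shifted by +0.9
in three marginal "NW" populations, all other populations keeping the
ancestral frequency; 68 climate variables as per-variable linear
loadings on standardized latitude/longitude plus N(0, 0.3) noise, the
first variable a growing-degree-days analogue with a strong negative
latitude loading; and a damage trait with 100 causal SNPs scaled to
within-population marker heritability 0.56, a latitude-linear
population shift scaled so the latent between/within ratio hits
Q_ST = 0.8 exactly, DDI effect −0.54, freezer-edge effect +0.1, total
within-population latent SD 0.4 (chosen so expected scores stay inside
0–6 at realistic Q_ST; larger values push most scores to the ceiling
and no estimator could recover the variance). Seedling counts per
population for the phenotype arm are a free choice (the source design
reports only totals); recovery experiments use 100 per population.
The Balding–Nichols choice trades coalescent realism for analytic
control — at F ≈ 0.004 frequency-level realism is all the downstream
estimators see. Populations sit on a jittered grid, not at the real
(unpublished) coordinates.

Deliberately absent: linkage disequilibrium between sites (free
recombination), genotyping error beyond the GQ/DP masks, spatially
autocorrelated residual environment, recolonization-route demography,
and ascertainment bias in SNP discovery. Passing tests therefore show
estimator correctness under the assumed statistical structure, not
robustness to those real-data features. An ordinal-threshold damage
generator (`damage_model = "ordinal"`) exists for model-misspecification
experiments.

## Numerical choices and degenerate inputs

Master seed → per-stage substreams via a Lehmer-style map
(`seed_stream`), keeping stages independently reproducible. F = 0
degenerates to identical population frequencies; Q_ST with both
variances zero is an error; sites with fewer than two genotyped
individuals in a population are skipped for that population's
statistics; pairs with < 50 overlapping sites are skipped in the
relatedness screen; zero-variance sites are dropped silently (counted)
in PCA and kinship; coincident coordinates are jittered with a warning
before PCNM; the 4-parameter logistic cline fit multi-starts over both
slope signs and three midpoints and errors only if every start fails.
Monomorphic SNPs are flagged and excluded from scan q-values. Ezekiel's
adjustment is used for every adjusted R².

## Known limitations

Q_ST is computed on the latent log scale; a response-scale Q_ST would
differ when means vary strongly. The single-chain split-R̂ is a weaker
diagnostic than true multi-chain R̂. The BSLMM's γ moves are local;
with thousands of tightly correlated large effects the sparse-set
posterior would mix slowly (the study-scale architectures used here
have at most a few). The permutation threshold conditions on the null
variance ratio. π normalization takes callable-site totals on trust —
with a variants-only VCF those totals must come from upstream callable
masks.
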