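Package: qstfst
Title: Comparing Phenotypic and Genomic Differentiation in Spatially
    Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow contrasting quantitative-trait
    differentiation (Q_ST) of seedling autumn frost damage with genomic
    differentiation across weakly structured populations. Provides a
    hierarchical Poisson MCMC for common-garden damage scores with
    posterior Q_ST, Weir-Cockerham F_ST and per-population diversity
    statistics with permutation tests, redundancy-analysis
    genotype-environment association with spatial (PCNM) variance
    partitioning and an RDA-axis outlier scan, kinship-corrected linear
    mixed model and Bayesian sparse linear mixed model association
    mapping, genotype filtering from VCF, and a synthetic
    genotype-environment-phenotype generator so that every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    permute,
    stats,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    lme4,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
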