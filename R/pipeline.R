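# Configuration-driven orchestration of the full workflow:
# simulate -> filter -> diversity/structure -> Q_ST -> GEA -> association.
# Every stage writes plain TSV/JSON so any stage can be re-run standalone;
# a manifest records seeds and parameters.

#' Default pipeline configuration
#'
#' @param seed master seed (stage seeds derive from it).
#' @param outdir output directory.
#' @param ... overrides for any top-level entry: `sim` (arguments to
#'   [sim_config()]), `stages` (named logical toggles), `qst`
#'   (iters/burnin/thin/h2), `gea` (n_perm, alpha), `assoc`
#'   (n_perm, bslmm_iters, bslmm_burnin, max_sparse).
#' @return a nested configuration list.
#' @export
pipeline_config <- function(seed = 1, outdir = "results", ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    stages = list(simulate = TRUE, filter = TRUE, diversity = TRUE,
                  structure = TRUE, qst = TRUE, gea = TRUE, assoc = TRUE),
    sim = list(),
    qst = list(iters = 4000, burnin = 2000, thin = 2, h2 = 1),
    gea = list(n_perm = 499, alpha = 0.05),
    assoc = list(n_perm = 200, bslmm_iters = 6000, bslmm_burnin = 2000,
                 max_sparse = 500)
  )
  mod <- list(...)
  for (nm in names(mod)) {
    cfg[[nm]] <- if (is.list(mod[[nm]]) && is.list(cfg[[nm]])) {
      utils::modifyList(cfg[[nm]], mod[[nm]])
    } else mod[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()]
#'   entries.
#' @return a configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated dataset
#' and writes: the genotype VCF and metadata tables, a diversity table
#' (H_o, H_e, permutation F_IS per population), the pairwise F_ST matrix
#' and global estimate, the Q_ST posterior summary, the GEA variance
#' partition and RDA outlier list, association scan results and BSLMM
#' hyperparameter estimates, and a run manifest. A stage failure halts
#' with the stage name; outputs of completed stages persist.
#'
#' @param config from [pipeline_config()] / [read_pipeline_config()].
#' @return (invisibly) a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f, rn = FALSE) utils::write.table(
    x, file.path(config$outdir, f), sep = "\t", quote = FALSE,
    row.names = rn, col.names = if (rn) NA else TRUE)
  jsn <- function(x, f) jsonlite::write_json(
    x, file.path(config$outdir, f), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  res <- list()
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list())
  stage <- function(name, expr) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(done = TRUE)
    out
  }

  res$sim <- stage("simulate", {
    sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                config$sim))
    gsim <- simulate_genotypes(sc)
    env <- simulate_environment(sc)
    dmg <- simulate_damage(sc, gsim$genotypes, gsim$truth)
    sim <- list(genotypes = gsim$genotypes, truth = dmg$truth,
                env = env$env, coords = env$coords, damage = dmg$damage)
    write_dataset(sim, config$outdir)
    manifest$sim_config <- unclass(sc)
    sim
  })

  res$filtered <- stage("filter", {
    g <- mask_low_quality(res$sim$genotypes)
    fl <- filter_sites(g)
    jsn(fl$report, "filter_report.json")
    fl$genotypes
  })
  gflt <- res$filtered %||% res$sim$genotypes

  res$diversity <- stage("diversity", {
    het <- het_stats(gflt)
    fis <- fis_permutation(gflt, n_perm = 199)
    div <- merge(het, fis, by = "population", all.x = TRUE, sort = FALSE)
    tsv(div, "diversity.tsv")
    div
  })

  res$structure <- stage("structure", {
    set.seed(seed_stream(config$seed, 21L))
    fst <- wc_fst(gflt)
    tsv(round(fst$pairwise, 6), "fst_pairwise.tsv", rn = TRUE)
    geo <- as.matrix(stats::dist(
      res$sim$coords[, c("latitude", "longitude")]))
    ibd <- ibd_regression(fst$pairwise, geo, n_perm = 499)
    pca <- genotype_pca(gflt, n_axes = 4)
    jsn(list(global_fst = fst$global, ibd = ibd,
             pc_var_frac = pca$var_frac), "structure.json")
    list(fst = fst, ibd = ibd, pca = pca)
  })

  res$qst <- stage("qst", {
    q <- config$qst
    post <- fit_damage_model(res$sim$damage, coords = res$sim$coords,
                             iters = q$iters, burnin = q$burnin,
                             thin = q$thin, h2 = q$h2,
                             seed = seed_stream(config$seed, 22L))
    lsm <- ls_means(post)
    tsv(data.frame(population = names(lsm), ls_mean = lsm),
        "ls_means.tsv")
    jsn(list(qst = post$qst_estimate, hpdi = as.list(post$qst_hpdi),
             sigmaB2 = mean(post$sigmaB2), sigmaW2 = mean(post$sigmaW2),
             h2 = post$h2), "qst_summary.json")
    list(posterior = post, ls_means = lsm)
  })

  res$gea <- stage("gea", {
    set.seed(seed_stream(config$seed, 23L))
    Y <- pop_allele_freqs(gflt)
    pc <- pcnm_axes(res$sim$coords)
    np <- config$gea$n_perm
    sel_env <- forward_select(Y, res$sim$env, alpha = config$gea$alpha,
                              n_perm = np)
    sel_geo <- forward_select(Y, pc$vectors, alpha = config$gea$alpha,
                              n_perm = np)
    env_df <- .as_pred_df(res$sim$env, "env")
    geo_df <- .as_pred_df(pc$vectors, "geo")
    if (!length(sel_env)) sel_env <- colnames(env_df)[1]
    if (!length(sel_geo)) sel_geo <- colnames(geo_df)[1]
    vp <- variance_partition(Y, env_df[, sel_env, drop = FALSE],
                             geo_df[, sel_geo, drop = FALSE])
    renv <- rda_gea(Y, env_df[, sel_env, drop = FALSE], n_perm = np)
    n_sig <- max(1, sum(renv$axis_p <= 0.05, na.rm = TRUE))
    out <- rda_outliers(renv, n_axes = min(n_sig, renv$rank))
    jsn(vp, "gea_partition.json")
    tsv(out[out$outlier, , drop = FALSE], "rda_outliers.tsv")
    list(selected_env = sel_env, selected_geo = sel_geo, partition = vp,
         rda = renv, outliers = out)
  })

  res$assoc <- stage("assoc", {
    dmg <- res$sim$damage
    i <- match(gflt$samples$id, dmg$seedling)
    y <- quantile_normalize(dmg$score[i],
                            interaction(dmg$rep[i], dmg$ddi[i]))
    K <- kinship_centered(gflt)
    scan <- lmm_scan(y, gflt, K)
    thr <- perm_threshold(y, gflt, K, n_perm = config$assoc$n_perm,
                          seed = seed_stream(config$seed, 24L),
                          scan = scan)
    bs <- bslmm(y, gflt, K, iters = config$assoc$bslmm_iters,
                burnin = config$assoc$bslmm_burnin,
                max_sparse = config$assoc$max_sparse,
                seed = seed_stream(config$seed, 25L))
    tsv(scan$snps, "assoc_lmm.tsv")
    tsv(cbind(hyperparameter = rownames(bs$estimates), bs$estimates),
        "bslmm_estimates.tsv")
    jsn(list(perm_threshold = thr$threshold,
             n_below_threshold = sum(scan$snps$p <= thr$threshold,
                                     na.rm = TRUE)),
        "assoc_summary.json")
    list(scan = scan, threshold = thr, bslmm = bs)
  })

  manifest$finished <- format(Sys.time())
  manifest$config <- config
  jsn(manifest, "manifest.json")
  res$manifest <- manifest
  invisible(res)
}
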