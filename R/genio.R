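#' Genotype matrix container
#'
#' Lightweight container for a diploid biallelic SNP matrix: alternate-allele
#' dosages in `{0, 1, 2, NA}` (individuals x sites) plus site and sample
#' metadata and, when available, per-call genotype quality (GQ) and read
#' depth (DP).
#'
#' @param calls integer matrix, individuals x sites, values 0/1/2/NA.
#' @param sites data.frame with columns `id, chrom, pos, ref, alt, biallelic`.
#' @param samples data.frame with columns `id, population`.
#' @param gq,dp optional numeric matrices of the same dimension as `calls`.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, sites, samples, gq = NULL, dp = NULL) {
  calls <- as.matrix(calls)
  .need_cols(sites, c("id", "chrom", "pos", "ref", "alt"), "site table")
  .need_cols(samples, c("id", "population"), "sample table")
  if (is.null(sites$biallelic)) sites$biallelic <- TRUE
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(sites))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  rownames(calls) <- samples$id
  colnames(calls) <- sites$id
  for (m in list(gq, dp)) {
    if (!is.null(m)) stopifnot(all(dim(m) == dim(calls)))
  }
  structure(
    list(calls = calls, sites = sites, samples = samples, gq = gq, dp = dp),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d sites (%d populations, %.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$samples$population)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# internal: subset a geno_matrix by individual / site index
subset_geno <- function(g, ind = NULL, site = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(g$calls))
  if (is.null(site)) site <- seq_len(ncol(g$calls))
  geno_matrix(
    g$calls[ind, site, drop = FALSE],
    g$sites[site, , drop = FALSE],
    g$samples[ind, , drop = FALSE],
    gq = if (!is.null(g$gq)) g$gq[ind, site, drop = FALSE],
    dp = if (!is.null(g$dp)) g$dp[ind, site, drop = FALSE]
  )
}

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT calls to alternate-allele dosage; `./.` becomes missing.
#' GQ and DP are captured when present in FORMAT. Multi-allelic records are
#' retained but flagged `biallelic = FALSE` (they are removed by
#' [filter_sites()]).
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param pop_map optional data.frame `id, population`; defaults to one
#'   population named "pop1".
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field", call. = FALSE)
  # vcfR returns sites x samples; transpose to individuals x sites
  gt_raw <- t(gt_raw)
  hap <- grepl("^[0-9.]$", gt_raw) & !is.na(gt_raw)
  if (any(hap)) stop("haploid GT calls are not supported", call. = FALSE)
  alleles <- function(k) {
    a <- substr(gt_raw, k, k)
    a[a == "."] <- NA
    suppressWarnings(as.integer(a))
  }
  a1 <- alleles(1); a2 <- alleles(3)
  calls <- matrix((a1 > 0) + (a2 > 0), nrow = nrow(gt_raw))
  calls[is.na(a1) | is.na(a2)] <- NA
  storage.mode(calls) <- "integer"
  num_mat <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) NULL else t(m)
  }
  fmt <- v@gt[, 1]
  gq <- if (any(grepl("GQ", fmt))) num_mat("GQ") else NULL
  dp <- if (any(grepl("DP", fmt))) num_mat("DP") else NULL
  sites <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    biallelic = !grepl(",", fix$ALT),
    stringsAsFactors = FALSE
  )
  ids <- rownames(gt_raw)
  if (is.null(pop_map)) {
    samples <- data.frame(id = ids, population = "pop1",
                          stringsAsFactors = FALSE)
  } else {
    .need_cols(pop_map, c("id", "population"), "population map")
    samples <- data.frame(
      id = ids,
      population = pop_map$population[match(ids, pop_map$id)],
      stringsAsFactors = FALSE
    )
  }
  geno_matrix(calls, sites, samples, gq = gq, dp = dp)
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' Emits GT:GQ:DP when quality matrices are present, GT otherwise.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  n <- nrow(g$calls); p <- ncol(g$calls)
  gt <- matrix("./.", n, p)
  idx <- !is.na(g$calls)
  gt[idx] <- gt_code[g$calls[idx] + 1L]
  has_q <- !is.null(g$gq) && !is.null(g$dp)
  if (has_q) {
    fmt_num <- function(m) {
      s <- matrix(as.character(m), n, p)
      s[is.na(m)] <- "."
      s
    }
    gt <- matrix(paste(gt, fmt_num(g$gq), fmt_num(g$dp), sep = ":"), n, p)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=qstfst",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_q) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    if (has_q) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$id), collapse = "\t")
  )
  body <- paste(
    g$sites$chrom, g$sites$pos, g$sites$id, g$sites$ref, g$sites$alt,
    ".", "PASS", ".", if (has_q) "GT:GQ:DP" else "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Mask low-quality genotype calls
#'
#' Calls with genotype quality below `gq_min` or read depth below `dp_min`
#' are set missing (strict thresholds: a call with GQ = 20 and DP = 5 under
#' the defaults is retained). A no-op with a warning when the matrix carries
#' no GQ/DP.
#'
#' @param g a [geno_matrix()].
#' @param gq_min,dp_min masking thresholds (mask iff GQ < gq_min or
#'   DP < dp_min).
#' @return a [geno_matrix()] with failing calls set missing.
#' @export
mask_low_quality <- function(g, gq_min = 20, dp_min = 5) {
  if (is.null(g$gq) && is.null(g$dp)) {
    warning("no GQ/DP present; mask_low_quality is a no-op")
    return(g)
  }
  bad <- matrix(FALSE, nrow(g$calls), ncol(g$calls))
  if (!is.null(g$gq)) bad <- bad | (!is.na(g$gq) & g$gq < gq_min)
  if (!is.null(g$dp)) bad <- bad | (!is.na(g$dp) & g$dp < dp_min)
  g$calls[bad] <- NA
  g
}

#' Filter sites by the standard post-calling rules
#'
#' Removal rules are applied in a fixed order, each site attributed to the
#' first rule it trips: not biallelic, monomorphic (among non-missing
#' calls), missing rate > `max_missing`, observed heterozygote fraction >
#' `max_het`, minor allele frequency < `min_maf` (strict; MAF exactly at the
#' threshold is retained). MAF is computed on non-missing calls pooled over
#' all individuals.
#'
#' @param g a [geno_matrix()] (quality masking already applied).
#' @param max_missing maximum tolerated missing-call fraction per site.
#' @param max_het maximum observed heterozygote fraction per site.
#' @param min_maf minimum minor allele frequency (strict lower bound).
#' @return list with elements `genotypes` (filtered [geno_matrix()]) and
#'   `report` (per-rule removal counts; counts sum to the input site count).
#' @export
filter_sites <- function(g, max_missing = 0.30, max_het = 0.70,
                         min_maf = 0.05) {
  calls <- g$calls
  n_sites <- ncol(calls)
  n_obs <- colSums(!is.na(calls))
  miss_rate <- 1 - n_obs / nrow(calls)
  p_alt <- ifelse(n_obs > 0, colSums(calls, na.rm = TRUE) / (2 * n_obs), NA)
  maf <- pmin(p_alt, 1 - p_alt)
  het <- ifelse(n_obs > 0, colSums(calls == 1L, na.rm = TRUE) / n_obs, NA)
  mono <- n_obs == 0 | p_alt %in% c(0, 1)

  rule <- rep(NA_character_, n_sites)
  hit <- function(cond, name) {
    take <- is.na(rule) & cond
    rule[take] <<- name
  }
  hit(!g$sites$biallelic, "non_biallelic")
  hit(mono, "monomorphic")
  hit(miss_rate > max_missing, "missing")
  hit(!is.na(het) & het > max_het, "excess_het")
  hit(!is.na(maf) & maf < min_maf, "low_maf")

  keep <- is.na(rule)
  report <- list(
    input = n_sites,
    removed = list(
      non_biallelic = sum(rule == "non_biallelic", na.rm = TRUE),
      monomorphic = sum(rule == "monomorphic", na.rm = TRUE),
      missing = sum(rule == "missing", na.rm = TRUE),
      excess_het = sum(rule == "excess_het", na.rm = TRUE),
      low_maf = sum(rule == "low_maf", na.rm = TRUE)
    ),
    survivors = sum(keep)
  )
  if (report$survivors == 0) {
    warning("no sites survive filtering")
  }
  list(genotypes = subset_geno(g, site = which(keep)), report = report)
}
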