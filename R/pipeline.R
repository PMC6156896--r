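## Orchestration: run configuration, end-to-end subcommands (simulate ->
## scan -> meQTL) with structured logging and deterministic text artifacts,
## plus a minimal command-line front end.

#' Pipeline run configuration
#'
#' Defaults equal the analysis parameters of the treatment-response study:
#' 5% window fraction, MAF locus-weight threshold 0.05, HD thresholds 0.9
#' intensity / 5 Mb, LD pruning at r^2 < 0.2, top-10 principal components,
#' alpha 0.05.
#'
#' @param window_fraction sliding-window size as a fraction of chromosome
#'   SNPs.
#' @param maf_threshold locus-weight MAF threshold.
#' @param degree local polynomial degree.
#' @param hd_intensity,hd_length_bp HD region thresholds.
#' @param r2_max LD pruning threshold.
#' @param n_pcs number of principal components.
#' @param index metabolic-syndrome covariate for this run: `"atp"` or
#'   `"idf"`.
#' @param alpha family-wise error rate.
#' @param missing_policy TG missing-visit policy, see [tg_response()].
#' @param cis_margin_bp margin around the window span defining the cis set.
#' @param sim a [sim_config()] used by [run_simulate()].
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(window_fraction = 0.05, maf_threshold = 0.05,
                       degree = 1L, hd_intensity = 0.9, hd_length_bp = 5e6,
                       r2_max = 0.2, n_pcs = 10L,
                       index = c("atp", "idf"), alpha = 0.05,
                       missing_policy = c("available", "complete"),
                       cis_margin_bp = 1e6, sim = NULL, seed = 1L) {
  cfg <- list(window_fraction = window_fraction,
              maf_threshold = maf_threshold, degree = as.integer(degree),
              hd_intensity = hd_intensity, hd_length_bp = hd_length_bp,
              r2_max = r2_max, n_pcs = as.integer(n_pcs),
              index = match.arg(index), alpha = alpha,
              missing_policy = match.arg(missing_policy),
              cis_margin_bp = cis_margin_bp,
              sim = sim %||% sim_config(seed = seed), seed = as.integer(seed))
  for (nm in c("window_fraction", "maf_threshold", "hd_intensity", "alpha"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stopf("invalid config field: %s", nm)
  class(cfg) <- "run_config"
  cfg
}

#' Generate and write a synthetic dataset
#'
#' Writes genotypes (VCF + fam sidecar), phenotypes, methylation matrices and
#' annotation, the planted-truth sidecar, the resolved configuration and a
#' manifest with md5 checksums.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory dataset (`genotypes`,
#'   `truth`, `phenotypes`, `meth`, `manifest`).
#' @export
run_simulate <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stopf("output directory not writable: %s", dir)
  sim <- config$sim
  log_stage("simulate", seed = sim$seed)
  g <- simulate_genotypes(sim)
  pheno <- simulate_phenotypes(g$genotypes, g$truth, sim)
  me <- simulate_methylation(g$genotypes, g$truth, sim)

  paths <- file.path(dir, c(
    vcf = "genotypes.vcf", fam = "pedigree.fam", pheno = "phenotypes.tsv",
    meth_v2 = "methylation_v2.tsv", meth_v4 = "methylation_v4.tsv",
    annot = "methylation_annot.tsv", truth = "truth.tsv",
    config = "config.json"))
  names(paths) <- c("vcf", "fam", "pheno", "meth_v2", "meth_v4", "annot",
                    "truth", "config")
  write_vcf(g$genotypes, paths["vcf"])
  write.table(data.frame(g$genotypes$pedigree, g$genotypes$samples,
                         0L, 0L, 0L, -9L),
              paths["fam"], quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  write_tsv(as.data.frame(pheno), paths["pheno"])
  for (v in c("v2", "v4")) {
    b <- me$meth$beta[[v]]
    write_tsv(data.frame(cpg = rownames(b), b, check.names = FALSE),
              paths[paste0("meth_", v)])
  }
  write_tsv(me$meth$annot, paths["annot"])
  truth_df <- data.frame(sample = g$genotypes$samples,
                         true_intensity = g$truth$true_intensity %||%
                           rep(NA_real_, length(g$genotypes$samples)))
  truth_df$carrier <- truth_df$sample %in%
    (if (nrow(g$truth$segments)) g$truth$segments$sample else character())
  write_tsv(truth_df, paths["truth"])
  jsonlite::write_json(
    list(seed = sim$seed, beta_hd = sim$tg_model$beta_hd,
         cis_effect = me$cis_effect, cis_cpgs = me$cis_cpgs,
         effect_region = g$truth$effect_region,
         run = config[setdiff(names(config), "sim")]),
    paths["config"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(package = "hdscan",
         version = as.character(packageVersion("hdscan")),
         seed = sim$seed, files = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  log_stage("simulate", n_samples = length(g$genotypes$samples),
            n_snps = nrow(g$genotypes$snp_map), files = nrow(manifest) + 1L)
  invisible(list(genotypes = g$genotypes, truth = g$truth, phenotypes = pheno,
                 meth = me$meth, cis_cpgs = me$cis_cpgs,
                 manifest = manifest))
}

## Shared stage: intensity profile + PCs + aligned model pieces.
prepare_scan_inputs <- function(config, gm, pheno) {
  m <- match(gm$samples, pheno$sample)
  if (anyNA(m)) stopf("samples missing from phenotype table")
  pheno <- pheno[m, ]
  ind <- homozygosity_indicator(gm)
  maf <- snp_maf(gm)
  win <- build_windows(gm$snp_map, config$window_fraction)
  prof <- estimate_intensity(ind, win, locus_weights(maf, config$maf_threshold),
                             degree = config$degree)
  log_stage("profile", n_windows = ncol(prof$H), n_samples = nrow(prof$H))
  pruned <- ld_prune(gm, r2_max = config$r2_max)
  log_stage("ld_prune", n_in = nrow(gm$snp_map), n_out = length(pruned))
  pcs <- compute_pcs(gm, pruned, k = config$n_pcs)
  list(profile = prof, pcs = pcs, pheno = pheno)
}

#' Run the genome-wide homozygosity association scan
#'
#' Executes profile -> LD pruning -> PCs -> per-window GEE -> effective-test
#' multiplicity -> Manhattan artifacts, and HD-region extraction.
#'
#' @param config a [run_config()] (its `index` field names the run).
#' @param dir directory holding a dataset written by [run_simulate()] (or
#'   files of the same layout); artifacts are written next to it.
#' @param data optional in-memory dataset (as returned by [run_simulate()])
#'   to skip re-reading files.
#' @return the `scan_result`, with the intensity profile and HD regions
#'   attached as attributes.
#' @export
run_scan <- function(config, dir, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) {
    gm <- read_genotypes(file.path(dir, "genotypes.vcf"), "vcf",
                         fam = file.path(dir, "pedigree.fam"))
    pheno <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  } else {
    gm <- data$genotypes; pheno <- data$phenotypes
  }
  inp <- prepare_scan_inputs(config, gm, pheno)
  resp <- tg_response(inp$pheno, config$missing_policy)
  log_stage("response", n_defined = sum(!is.na(resp)))
  covar <- covariate_design(inp$pheno, inp$pcs$scores, config$index)
  scan <- genome_scan(inp$profile, resp, covar, gm$pedigree,
                      alpha = config$alpha)
  log_stage("scan", n_testable = sum(scan$table$testable),
            n_e_total = scan$n_e_total,
            n_significant = length(scan$significant))
  regions <- extract_hd_regions(inp$profile, config$hd_intensity,
                                config$hd_length_bp)
  tag <- config$index
  write_tsv(scan$table, file.path(dir, sprintf("scan_%s.tsv", tag)))
  write_tsv(scan$per_chrom, file.path(dir, sprintf("multiplicity_%s.tsv", tag)))
  manhattan_table(scan, file.path(dir, sprintf("manhattan_%s.png", tag)))
  write_regions(regions, file.path(dir, "hd_regions.bed"))
  write_tsv(summarize_hd(regions), file.path(dir, "hd_summary.tsv"))
  attr(scan, "profile") <- inp$profile
  attr(scan, "pcs") <- inp$pcs
  attr(scan, "regions") <- regions
  attr(scan, "pheno") <- inp$pheno
  scan
}

#' Run the meQTL follow-up for selected windows
#'
#' BMIQ normalization -> M-value responses -> cis and trans GEE scans for
#' each selected window (default: the windows passing the genome-wide
#' threshold in `scan`).
#'
#' @param config a [run_config()].
#' @param dir dataset/artifact directory.
#' @param scan a `scan_result` from [run_scan()] (with attached profile).
#' @param windows window IDs to follow up; default `scan$significant`.
#' @param data optional in-memory dataset from [run_simulate()].
#' @param meth optional pre-normalized [methylation_set()] (cache) to skip
#'   BMIQ.
#' @return list with one element per window: `cis` (data frame) and `trans`
#'   (list from [trans_scan()]); plus the normalized set as attribute
#'   `meth_normalized`.
#' @export
run_meqtl <- function(config, dir, scan, windows = NULL, data = NULL,
                      meth = NULL) {
  stopifnot(inherits(config, "run_config"))
  windows <- windows %||% scan$significant
  if (!length(windows)) stopf("nothing to test: no significant windows and no override")
  prof <- attr(scan, "profile")
  pheno <- attr(scan, "pheno")
  pcs <- attr(scan, "pcs")
  if (is.null(prof)) stopf("scan lacks its attached profile; rerun run_scan()")
  if (is.null(meth)) {
    raw <- if (!is.null(data)) data$meth else
      read_methylation(c(v2 = file.path(dir, "methylation_v2.tsv"),
                         v4 = file.path(dir, "methylation_v4.tsv")),
                       file.path(dir, "methylation_annot.tsv"))
    meth <- bmiq_normalize(raw)
  }
  log_stage("meqtl", n_cpgs = nrow(meth$annot), n_windows = length(windows))
  resp <- methylation_response(meth)
  keep <- match(colnames(resp), pheno$sample)
  if (anyNA(keep)) stopf("methylation samples missing from phenotype table")
  covar <- covariate_design(pheno[keep, ], pcs$scores[keep, , drop = FALSE],
                            config$index)
  clusters <- pheno$pedigree[keep]
  wtab <- prof$windows$windows
  out <- list()
  for (w in windows) {
    row <- wtab[wtab$window == w, ]
    if (!nrow(row)) stopf("unknown window ID: %s", w)
    span <- list(chrom = row$chrom,
                 start = prof$windows$snp_map$pos[row$first],
                 end = prof$windows$snp_map$pos[row$last])
    sets <- define_cis_set(meth$annot, span, margin_bp = config$cis_margin_bp)
    h <- prof$H[keep, wtab$window == w]
    cis <- if (length(sets$cis))
      cis_scan(h, resp, sets$cis, covar, clusters) else NULL
    trans <- if (length(sets$trans))
      trans_scan(h, resp, sets$trans, covar, clusters, alpha = config$alpha)
      else NULL
    tag <- sprintf("meqtl_w%s_%s", w, config$index)
    comb <- rbind(cis, if (!is.null(trans)) trans$table)
    if (!is.null(comb)) write_tsv(comb, file.path(dir, paste0(tag, ".tsv")))
    out[[as.character(w)]] <- list(window = row, cis = cis, trans = trans)
  }
  attr(out, "meth_normalized") <- meth
  out
}

#' Minimal command-line front end
#'
#' Subcommands: `simulate`, `scan`, `meqtl`, `report`. Typical use:
#' `Rscript -e 'hdscan::hdscan_cli()' scan --dir out --index atp --seed 1`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
hdscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hdscan <simulate|scan|meqtl|report> --dir DIR [--seed N] [--index atp|idf] [--windows w1,w2]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(dir = "hdscan_out", seed = 1L, index = "atp", windows = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) { message("unknown option: ", args[i]); return(invisible(2L)) }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- run_config(index = opt$index, seed = as.integer(opt$seed),
                    sim = sim_config(seed = as.integer(opt$seed)))
  status <- tryCatch({
    switch(cmd,
      simulate = { run_simulate(cfg, opt$dir); 0L },
      scan = { run_scan(cfg, opt$dir); 0L },
      meqtl = {
        scan <- run_scan(cfg, opt$dir)
        w <- if (!is.null(opt$windows))
          as.integer(strsplit(opt$windows, ",")[[1]]) else NULL
        run_meqtl(cfg, opt$dir, scan, windows = w); 0L
      },
      report = {
        f <- file.path(opt$dir, "manifest.json")
        if (!file.exists(f)) stopf("no manifest in %s", opt$dir)
        cat(readLines(f), sep = "\n"); 0L
      },
      { message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
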