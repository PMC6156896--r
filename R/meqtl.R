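## meQTL arm: cis/trans partition of CpGs relative to an HD window and GEE
## tests of window intensity against per-CpG methylation response. The test
## shares the GEE code path with the genotype scan by contract.

#' Partition CpGs into cis and trans for a region
#'
#' @param annot CpG annotation data frame (`cpg`, `chrom`, `pos`).
#' @param region list or one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive) — a gene span or an HD window span.
#' @param margin_bp extension added to both sides of the region (default 0).
#' @return list with character vectors `cis` and `trans`; the two sets
#'   partition the annotated CpGs.
#' @export
define_cis_set <- function(annot, region, margin_bp = 0) {
  if (!nrow(annot)) stopf("empty CpG annotation")
  in_reg <- annot$chrom == as.character(region$chrom) &
    annot$pos >= region$start - margin_bp &
    annot$pos <= region$end + margin_bp
  list(cis = annot$cpg[in_reg], trans = annot$cpg[!in_reg])
}

#' GEE meQTL test for one (window, CpG) pair
#'
#' Identical model contract to [gee_window_test()] with the CpG's methylation
#' response as the outcome.
#'
#' @inheritParams gee_window_test
#' @param m_response per-sample M-value change for one CpG.
#' @return one-row data frame as in [gee_window_test()].
#' @export
meqtl_test <- function(h, m_response, covariates, clusters) {
  gee_window_test(h, m_response, covariates, clusters)
}

#' cis-meQTL scan for one window
#'
#' @param h per-sample window intensity.
#' @param responses CpG x sample matrix from [methylation_response()].
#' @param cis_cpgs CpG IDs to test (e.g. from [define_cis_set()]).
#' @param covariates,clusters as in [gee_window_test()].
#' @return data frame with one row per CpG (`cpg`, `scope`, then the
#'   [gee_window_test()] columns).
#' @export
cis_scan <- function(h, responses, cis_cpgs, covariates, clusters) {
  cpgs <- intersect(cis_cpgs, rownames(responses))
  if (!length(cpgs)) stopf("no cis CpGs to test")
  out <- do.call(rbind, lapply(cpgs, function(cg)
    meqtl_test(h, responses[cg, ], covariates, clusters)))
  cbind(data.frame(cpg = cpgs, scope = "cis", stringsAsFactors = FALSE), out)
}

#' trans-meQTL scan for one window
#'
#' Tests every trans CpG and applies a Bonferroni threshold of
#' `alpha / n_tested`.
#'
#' @param h per-sample window intensity.
#' @param responses CpG x sample matrix from [methylation_response()].
#' @param trans_cpgs CpG IDs considered trans.
#' @param covariates,clusters as in [gee_window_test()].
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `table` (per-CpG results, `scope = "trans"`),
#'   `n_tested`, `threshold`, `significant` (CpG IDs).
#' @export
trans_scan <- function(h, responses, trans_cpgs, covariates, clusters,
                       alpha = 0.05) {
  cpgs <- intersect(trans_cpgs, rownames(responses))
  if (!length(cpgs)) stopf("no trans CpGs to test")
  tab <- do.call(rbind, lapply(cpgs, function(cg)
    meqtl_test(h, responses[cg, ], covariates, clusters)))
  tab <- cbind(data.frame(cpg = cpgs, scope = "trans",
                          stringsAsFactors = FALSE), tab)
  n_tested <- sum(tab$testable)
  threshold <- alpha / max(n_tested, 1L)
  list(table = tab, n_tested = n_tested, threshold = threshold,
       significant = tab$cpg[!is.na(tab$p) & tab$p < threshold])
}
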