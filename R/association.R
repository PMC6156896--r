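## Genome-wide homozygosity association: TG response definition, per-window
## GEE Wald tests, the eigenvalue-based effective number of independent tests
## and the genome-wide significance threshold.

#' Triglyceride response to treatment
#'
#' Response = mean of the post-treatment visits (3, 4) minus the mean of the
#' pre-treatment visits (1, 2), in mg/dL; negative values mean TG lowering.
#'
#' @param pheno a [phenotype_table()].
#' @param policy `"available"` (default): average whatever visits are present
#'   on each side, missing only when a whole side is absent. `"complete"`:
#'   missing unless all four visits are present.
#' @return named numeric vector of responses (`NA` where undefined), in the
#'   order of `pheno$sample`.
#' @export
tg_response <- function(pheno, policy = c("available", "complete")) {
  policy <- match.arg(policy)
  pre <- as.matrix(pheno[c("tg1", "tg2")])
  post <- as.matrix(pheno[c("tg3", "tg4")])
  if (policy == "complete") {
    out <- rowMeans(post) - rowMeans(pre)
  } else {
    pre_m <- rowMeans(pre, na.rm = TRUE)
    post_m <- rowMeans(post, na.rm = TRUE)
    pre_m[rowSums(!is.na(pre)) == 0L] <- NA_real_
    post_m[rowSums(!is.na(post)) == 0L] <- NA_real_
    out <- post_m - pre_m
  }
  setNames(out, pheno$sample)
}

#' Build the covariate design for the association models
#'
#' Covariates follow the treatment-response model: sex, age, field center
#' (general categorical encoding), smoking, one metabolic-syndrome index (ATP
#' or IDF, one per run) and the top principal components.
#'
#' @param pheno a [phenotype_table()].
#' @param pcs samples x k matrix of PC scores aligned to `pheno$sample`
#'   (or `NULL` for none).
#' @param index `"atp"` or `"idf"`.
#' @return numeric covariate matrix (no intercept), rows aligned to `pheno`.
#' @export
covariate_design <- function(pheno, pcs = NULL, index = c("atp", "idf")) {
  index <- match.arg(tolower(index[1]), c("atp", "idf"))
  center <- factor(pheno$center)
  cen <- if (nlevels(center) > 1)
    stats::model.matrix(~center)[, -1, drop = FALSE] else NULL
  X <- cbind(sex = pheno$sex, age = pheno$age, cen,
             smoking = pheno$smoking, index = pheno[[index]])
  if (!is.null(pcs)) {
    if (nrow(pcs) != nrow(pheno)) stopf("PC rows do not match phenotype rows")
    X <- cbind(X, pcs)
  }
  rownames(X) <- pheno$sample
  X
}

#' GEE association test for one window
#'
#' Regresses the response on the window's homozygosity intensity plus
#' covariates under a Gaussian GEE with exchangeable working correlation by
#' pedigree and sandwich standard errors; reports the two-sided Wald p-value
#' for the intensity coefficient. Samples missing any model variable are
#' dropped listwise. The reported `se` is the classical sandwich; the p-value
#' uses small-sample inference (Mancl-DeRouen bias-corrected variance with a
#' t reference on clusters - parameters degrees of freedom), because with a
#' few dozen pedigrees the plain sandwich-normal Wald test badly inflates the
#' far tail that genome-wide (Bonferroni-scale) thresholds live in.
#'
#' @param h per-sample homozygosity intensity for the window.
#' @param response per-sample outcome (TG or methylation response).
#' @param covariates covariate matrix (no intercept), e.g. from
#'   [covariate_design()].
#' @param clusters pedigree ID per sample.
#' @return one-row data frame: `estimate`, `se`, `z`, `p`, `n`, `testable`,
#'   `converged`.
#' @export
gee_window_test <- function(h, response, covariates = NULL, clusters) {
  covariates <- if (is.null(covariates)) matrix(0, length(h), 0)
                else as.matrix(covariates)
  ok <- !is.na(h) & !is.na(response) & stats::complete.cases(covariates)
  na_row <- data.frame(estimate = NA_real_, se = NA_real_, z = NA_real_,
                       p = NA_real_, n = sum(ok), testable = FALSE,
                       converged = NA)
  if (sum(ok) < ncol(covariates) + 3L) return(na_row)
  if (length(unique(h[ok])) < 2L) return(na_row)   # constant intensity
  X <- cbind(`(Intercept)` = 1, intensity = h[ok], covariates[ok, , drop = FALSE])
  fit <- gee_fit(response[ok], X, clusters[ok])
  est <- fit$coefficients["intensity"]
  se <- fit$se["intensity"]
  z <- est / se
  t_md <- est / fit$se_md["intensity"]
  df <- max(1, fit$n_clusters - ncol(X))
  data.frame(estimate = unname(est), se = unname(se), z = unname(z),
             p = unname(2 * stats::pt(-abs(t_md), df)), n = fit$n,
             testable = TRUE, converged = fit$converged)
}

#' Effective number of independent tests for one chromosome
#'
#' Overlapping sliding windows make neighbouring tests strongly dependent.
#' With eigenvalues `lambda_i` of the correlation matrix of window
#' intensities, the effective count is
#' `n_e = n - sum_i I(lambda_i > 1) * (lambda_i - 1)`,
#' which equals `n` for independent windows and 1 for perfectly correlated
#' ones. Zero-variance windows are excluded from the matrix (and from `n`)
#' with a logged count; rows with missing intensities are dropped
#' (complete-case) so the matrix stays positive semi-definite.
#'
#' @param H samples x windows intensity matrix for one chromosome.
#' @return list with `n_e`, `lambda` (eigenvalues, descending), `n_used`
#'   (windows entering the matrix), `n_excluded`.
#' @export
effective_tests <- function(H) {
  H <- as.matrix(H)
  cc <- stats::complete.cases(H)
  Hc <- H[cc, , drop = FALSE]
  v <- apply(Hc, 2, var)
  use <- !is.na(v) & v > 0
  n_excluded <- sum(!use)
  if (n_excluded > 0) log_stage("effective_tests", zero_variance_windows = n_excluded)
  if (sum(use) < 2L) stopf("fewer than 2 usable windows")
  C <- cor(Hc[, use, drop = FALSE])
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)            # clip eigendecomposition round-off
  n_used <- sum(use)
  n_e <- n_used - sum((lambda - 1)[lambda > 1])
  list(n_e = n_e, lambda = lambda, n_used = n_used, n_excluded = n_excluded)
}

#' Genome-wide significance threshold
#'
#' Bonferroni at the effective number of independent tests:
#' `alpha / n_e_total`.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_e_total sum of per-chromosome effective test counts (>= 1).
#' @return the per-test significance threshold.
#' @export
significance_threshold <- function(alpha = 0.05, n_e_total) {
  if (n_e_total < 1) stopf("n_e_total must be >= 1")
  alpha / n_e_total
}

#' Genome-wide homozygosity association scan
#'
#' Applies [gee_window_test()] to every window of an intensity profile,
#' attaches per-chromosome effective-test counts and flags windows passing
#' the genome-wide threshold `alpha / sum_j n_e_j`.
#'
#' @param profile an `intensity_profile` (samples aligned to `response`).
#' @param response per-sample outcome, e.g. from [tg_response()].
#' @param covariates covariate matrix from [covariate_design()].
#' @param clusters pedigree IDs per sample.
#' @param alpha family-wise error rate (default 0.05).
#' @return object of class `scan_result`: list with `table` (per-window
#'   results), `per_chrom` (n windows, usable windows, `n_e`), `n_e_total`,
#'   `alpha`, `threshold`, `significant` (window IDs with `p < threshold`).
#' @export
genome_scan <- function(profile, response, covariates, clusters, alpha = 0.05) {
  wtab <- profile$windows$windows
  H <- profile$H
  res <- vector("list", nrow(wtab))
  for (w in seq_len(nrow(wtab)))
    res[[w]] <- gee_window_test(H[, w], response, covariates, clusters)
  tab <- cbind(wtab[c("window", "chrom", "anchor_id", "anchor_pos")],
               do.call(rbind, res))
  if (!any(tab$testable)) stopf("no testable windows")
  per_chrom <- lapply(unique(wtab$chrom), function(ch) {
    eff <- effective_tests(H[, wtab$chrom == ch, drop = FALSE])
    data.frame(chrom = ch, n_windows = sum(wtab$chrom == ch),
               n_used = eff$n_used, n_e = eff$n_e)
  })
  per_chrom <- do.call(rbind, per_chrom)
  n_e_total <- sum(per_chrom$n_e)
  threshold <- significance_threshold(alpha, n_e_total)
  structure(list(table = tab, per_chrom = per_chrom, n_e_total = n_e_total,
                 alpha = alpha, threshold = threshold,
                 significant = tab$window[!is.na(tab$p) & tab$p < threshold]),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d windows, n_e = %.1f, threshold = %.3g, %d significant\n",
              nrow(x$table), x$n_e_total, x$threshold, length(x$significant)))
  invisible(x)
}

#' Manhattan table and plot
#'
#' @param scan a `scan_result`.
#' @param file optional PNG path; when given, a Manhattan plot with the
#'   genome-wide threshold line is written there.
#' @return data frame (chrom, position, p, neglog10p), sorted by
#'   (chromosome, position).
#' @export
manhattan_table <- function(scan, file = NULL) {
  tab <- scan$table
  out <- data.frame(chrom = tab$chrom, pos = tab$anchor_pos, p = tab$p,
                    neglog10p = -log10(tab$p))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  if (!is.null(file)) {
    chroms <- unique(out$chrom)
    offs <- c(0, cumsum(vapply(chroms, function(ch)
      max(out$pos[out$chrom == ch]), 0)))[seq_along(chroms)]
    names(offs) <- chroms
    x <- out$pos + offs[as.character(out$chrom)]
    png(file, width = 1200, height = 500)
    on.exit(dev.off())
    plot(x, out$neglog10p, pch = 20, cex = 0.6,
         col = (match(out$chrom, chroms) %% 2) + 1,
         xlab = "genomic position", ylab = expression(-log[10](p)),
         main = "homozygosity association scan")
    abline(h = -log10(scan$threshold), lty = 2, col = "red")
  }
  out
}
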