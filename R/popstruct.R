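## Population-structure adjustment: greedy windowed LD pruning and PCA on
## frequency-standardized genotypes, run per chromosome / all samples.

#' Greedy windowed LD pruning
#'
#' Within each sliding block of `window_snps` SNPs (advanced by `step_snps`,
#' per chromosome), while any pair of retained SNPs has squared Pearson
#' correlation of genotype codes above `r2_max`, the later-indexed SNP of the
#' worst pair is removed. Correlations use pairwise-complete observations.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_max maximum allowed squared correlation (default 0.2).
#' @param window_snps block size in SNPs (default 50).
#' @param step_snps block advance in SNPs (default 5).
#' @return integer vector of retained SNP column indices (sorted).
#' @export
ld_prune <- function(gm, r2_max = 0.2, window_snps = 50L, step_snps = 5L) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else gm
  chrom <- if (inherits(gm, "genotype_matrix")) gm$snp_map$chrom
           else rep("1", ncol(g))
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    start <- 1L
    repeat {
      stop_ <- min(start + window_snps - 1L, n)
      block <- idx[start:stop_]
      block <- block[keep[block]]
      if (length(block) >= 2L) {
        r2 <- suppressWarnings(
          cor(g[, block, drop = FALSE], use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        repeat {
          worst <- which(r2 == max(r2), arr.ind = TRUE)
          if (max(r2) <= r2_max) break
          drop_local <- max(worst[1L, ])  # later-indexed SNP of the worst pair
          keep[block[drop_local]] <- FALSE
          r2[drop_local, ] <- 0; r2[, drop_local] <- 0
        }
      }
      if (stop_ >= n) break
      start <- start + step_snps
    }
  }
  which(keep)
}

#' Principal components of a genotype matrix
#'
#' SNP columns are centered at `2p` and scaled by `sqrt(2p(1-p))` (`p` =
#' sample allele frequency); missing entries become 0 after centering. The
#' top-`k` left singular vectors (scaled by their singular values) are the
#' sample scores.
#'
#' @param gm a [genotype_matrix()].
#' @param snps SNP column indices to use, e.g. from [ld_prune()]
#'   (default: all).
#' @param k number of components (default 10); silently capped at the matrix
#'   rank with a warning.
#' @return list with `scores` (samples x k), `varprop` (explained-variance
#'   fractions), `snps` (SNP indices used).
#' @export
compute_pcs <- function(gm, snps = NULL, k = 10L) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else gm
  if (is.null(snps)) snps <- seq_len(ncol(g))
  if (!length(snps)) stopf("empty SNP set")
  x <- g[, snps, drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  sdv <- sqrt(2 * p * (1 - p))
  use <- !is.na(sdv) & sdv > 0
  x <- x[, use, drop = FALSE]
  z <- sweep(x, 2, 2 * p[use])
  z <- sweep(z, 2, sdv[use], "/")
  z[is.na(z)] <- 0
  if (k == 0L)
    return(list(scores = matrix(0, nrow(z), 0), varprop = numeric(0),
                snps = snps[use]))
  sv <- svd(z)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > pos) {
    warnf("requested %d components but rank is %d", k, pos)
    k <- pos
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  ## Deterministic sign: largest-magnitude loading positive.
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, varprop = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       snps = snps[use])
}
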