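## Homozygosity-intensity profiling: nearest-neighbor sliding windows, the
## double-weight (kernel x locus) local polynomial smoother, and extraction of
## runs-of-homozygosity regions from the fitted profile.

#' Build nearest-neighbor sliding windows
#'
#' One window is anchored at every SNP. On a chromosome with `n_j` SNPs each
#' window holds `k_j = max(2, round(fraction * n_j))` SNPs (capped at `n_j`):
#' the anchor plus its nearest neighbors by physical distance, ties broken
#' toward the lower index. Because SNPs are position-sorted, every window is a
#' contiguous index block.
#'
#' @param snp_map data frame with `id`, `chrom`, `pos` (sorted within
#'   chromosome).
#' @param fraction window size as a proportion of the SNPs on the chromosome
#'   (default 0.05, i.e. 5%).
#' @return An object of class `window_set`: data frame `windows` with columns
#'   `window`, `chrom`, `anchor` (global SNP index), `anchor_id`, `anchor_pos`,
#'   `first`, `last` (global index range of members), `k`.
#' @export
build_windows <- function(snp_map, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  chroms <- unique(snp_map$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    idx <- which(snp_map$chrom == ch)
    n_j <- length(idx)
    if (n_j < 2) stopf("chromosome %s has fewer than 2 SNPs", ch)
    pos <- snp_map$pos[idx]
    k <- min(n_j, max(2L, as.integer(round(fraction * n_j))))
    first <- integer(n_j); last <- integer(n_j)
    for (i in seq_len(n_j)) {
      l <- i; r <- i
      for (m in seq_len(k - 1L)) {
        dl <- if (l > 1L) pos[i] - pos[l - 1L] else Inf
        dr <- if (r < n_j) pos[r + 1L] - pos[i] else Inf
        if (dl <= dr) l <- l - 1L else r <- r + 1L   # tie -> lower index
      }
      first[i] <- l; last[i] <- r
    }
    out[[ci]] <- data.frame(
      chrom = ch, anchor = idx, anchor_id = snp_map$id[idx], anchor_pos = pos,
      first = idx[first], last = idx[last], k = k, stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, out)
  windows$window <- seq_len(nrow(windows))
  windows <- windows[c("window", "chrom", "anchor", "anchor_id", "anchor_pos",
                       "first", "last", "k")]
  structure(list(windows = windows, snp_map = snp_map, fraction = fraction),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows over %d chromosome(s), fraction %.3g\n",
              nrow(x$windows), length(unique(x$windows$chrom)), x$fraction))
  invisible(x)
}

#' Homozygosity indicator matrix
#'
#' @param gm a [genotype_matrix()] or a genotype code matrix.
#' @return matrix of the same shape: 1 for homozygous codes (0 or 2), 0 for
#'   heterozygous (1), `NA` for missing.
#' @export
homozygosity_indicator <- function(gm) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else gm
  ind <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  ind[g == 0L | g == 2L] <- 1
  ind[g == 1L] <- 0
  ind
}

#' Per-SNP minor allele frequency
#'
#' Computed from the analysis sample itself; missing genotypes are excluded.
#'
#' @param gm a [genotype_matrix()] or code matrix.
#' @return numeric vector of MAFs in `[0, 0.5]`, `NA` for all-missing SNPs.
#' @export
snp_maf <- function(gm) {
  g <- if (inherits(gm, "genotype_matrix")) gm$genotypes else gm
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Locus weights from minor allele frequency
#'
#' Rare variants carry less homozygosity information: a common homozygote at a
#' rare SNP is almost guaranteed. The weight is a capped linear ramp,
#' `v = min(maf / threshold, 1)`, so SNPs at or above the MAF threshold get
#' full weight and monomorphic SNPs contribute nothing.
#'
#' @param maf per-SNP minor allele frequencies in `[0, 0.5]`.
#' @param threshold MAF at which the weight saturates (default 0.05).
#' @return numeric weights in `[0, 1]`.
#' @export
locus_weights <- function(maf, threshold = 0.05) {
  ok <- !is.na(maf)
  if (any(maf[ok] < 0 | maf[ok] > 0.5))
    stopf("MAF outside [0, 0.5]")
  w <- pmin(maf / threshold, 1)
  w[!ok] <- 0
  w
}

tricube <- function(u) ifelse(abs(u) <= 1, (1 - abs(u)^3)^3, 0)

## Local polynomial fit at u = 0 for one window: returns the linear functional
## a such that H = sum(a * x) for complete data, with rank-deficiency fallback
## to the weighted mean (degree 0).
window_functional <- function(u, w, degree) {
  if (degree > 0) {
    X <- outer(u, 0:degree, `^`)
    sw <- sqrt(w)
    qr_ <- qr(X * sw)
    if (qr_$rank == degree + 1L) {
      XtW <- t(X * w)
      a <- solve(XtW %*% X, XtW)[1L, ]
      return(a)
    }
  }
  w / sum(w)
}

#' Estimate homozygosity-intensity profiles
#'
#' For each sample and window, fits a weighted local polynomial of the
#' homozygosity indicator on scaled position `u = (pos - anchor)/h`, where the
#' bandwidth `h` is the largest in-window distance to the anchor, the kernel
#' weight is tricube `(1 - |u|^3)^3` and the locus weight down-weights rare
#' SNPs. The intensity is the fitted value at the anchor (`u = 0`), clipped to
#' `[0, 1]`. A rank-deficient weighted design falls back to the weighted mean.
#'
#' @param indicators homozygosity indicator matrix from
#'   [homozygosity_indicator()] (samples x SNPs; `NA` = missing genotype).
#' @param windows a `window_set` from [build_windows()] on the same SNP map.
#' @param weights per-SNP locus weights from [locus_weights()].
#' @param degree polynomial degree (default 1).
#' @return An object of class `intensity_profile`: list with `H` (samples x
#'   windows matrix in `[0, 1]`, `NA` where no usable genotype), `windows`,
#'   `weights`.
#' @export
estimate_intensity <- function(indicators, windows, weights, degree = 1L) {
  stopifnot(inherits(windows, "window_set"), degree >= 0L)
  wtab <- windows$windows
  n_snp <- ncol(indicators)
  if (length(weights) != n_snp)
    stopf("weights length (%d) != SNP count (%d)", length(weights), n_snp)
  pos <- windows$snp_map$pos
  n_w <- nrow(wtab)
  n_s <- nrow(indicators)

  ## Sparse projection for complete rows: H = indicators %*% A with one column
  ## of fit coefficients per window.
  ai <- vector("list", n_w); ax <- vector("list", n_w)
  usable <- rep(TRUE, n_w)
  for (w in seq_len(n_w)) {
    mem <- wtab$first[w]:wtab$last[w]
    u <- (pos[mem] - wtab$anchor_pos[w])
    h <- max(abs(u), 1)
    u <- u / h
    cw <- tricube(u) * weights[mem]
    if (sum(cw) <= 0) { usable[w] <- FALSE; next }
    keep <- cw > 0
    a <- window_functional(u[keep], cw[keep], degree)
    ai[[w]] <- mem[keep]; ax[[w]] <- a
  }
  lens <- lengths(ai)
  if (any(usable)) {
    A <- Matrix::sparseMatrix(i = as.integer(unlist(ai)),
                              j = rep(seq_len(n_w), lens),
                              x = as.numeric(unlist(ax)),
                              dims = c(n_snp, n_w))
    ind0 <- indicators; ind0[is.na(ind0)] <- 0
    H <- as.matrix(ind0 %*% A)
    H[, !usable] <- NA_real_
  } else {
    H <- matrix(NA_real_, n_s, n_w)
  }

  ## Rows with missing members are refit per (sample, window) pair.
  if (anyNA(indicators)) {
    na_ind <- matrix(as.numeric(is.na(indicators)), n_s, n_snp)
    M <- Matrix::sparseMatrix(i = unlist(lapply(seq_len(n_w), function(w)
           wtab$first[w]:wtab$last[w])),
           j = rep(seq_len(n_w), wtab$last - wtab$first + 1L),
           x = 1, dims = c(n_snp, n_w))
    hit <- which(as.matrix(na_ind %*% M) > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      s <- hit[r, 1L]; w <- hit[r, 2L]
      if (!usable[w]) next
      mem <- wtab$first[w]:wtab$last[w]
      x <- indicators[s, mem]
      ok <- !is.na(x)
      u <- (pos[mem] - wtab$anchor_pos[w])
      h <- max(abs(u), 1)
      cw <- tricube(u / h) * weights[mem]
      ok <- ok & cw > 0
      if (!any(ok)) { H[s, w] <- NA_real_; next }
      a <- window_functional((u / h)[ok], cw[ok], degree)
      H[s, w] <- sum(a * x[ok])
    }
  }
  H[] <- clamp(H, 0, 1)
  rownames(H) <- rownames(indicators)
  structure(list(H = H, windows = windows, weights = weights, degree = degree),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: %d samples x %d windows (degree %d)\n",
              nrow(x$H), ncol(x$H), x$degree))
  invisible(x)
}

#' Extract runs-of-homozygosity (HD) regions from an intensity profile
#'
#' Per sample and chromosome, maximal runs of consecutive windows whose
#' intensity meets `min_intensity` are merged into regions spanning the
#' first-to-last anchor position; regions shorter than `min_length_bp` are
#' discarded. Defaults are intensity >= 0.9 over >= 5 Mb.
#'
#' @param profile an `intensity_profile`.
#' @param min_intensity intensity threshold (default 0.9).
#' @param min_length_bp minimum region length in bp (default 5e6).
#' @return data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `length` (1-based inclusive, so `end - start + 1`), `n_windows`,
#'   `mean_intensity`.
#' @export
extract_hd_regions <- function(profile, min_intensity = 0.9,
                               min_length_bp = 5e6) {
  wtab <- profile$windows$windows
  H <- profile$H
  samples <- rownames(H) %||% as.character(seq_len(nrow(H)))
  res <- list()
  for (ch in unique(wtab$chrom)) {
    wi <- which(wtab$chrom == ch)
    anchors <- wtab$anchor_pos[wi]
    sub <- H[, wi, drop = FALSE]
    for (s in seq_len(nrow(sub))) {
      hot <- !is.na(sub[s, ]) & sub[s, ] >= min_intensity
      if (!any(hot)) next
      r <- rle(hot)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        start <- anchors[starts[k]]; end <- anchors[ends[k]]
        len <- end - start + 1
        if (len < min_length_bp) next
        res[[length(res) + 1L]] <- data.frame(
          sample = samples[s], chrom = ch, start = start, end = end,
          length = len, n_windows = ends[k] - starts[k] + 1L,
          mean_intensity = mean(sub[s, starts[k]:ends[k]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_windows = integer(), mean_intensity = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Five-number summaries of HD region lengths
#'
#' Summarizes individual region lengths and per-sample total HD length with
#' the five-number summary (min, Q1, median, Q3, max; quantile type 7).
#'
#' @param regions data frame from [extract_hd_regions()].
#' @return data frame with rows `region_length` and `per_genome_total` and
#'   columns `n`, `min`, `q1`, `median`, `q3`, `max` (bp). Empty input gives a
#'   0-row frame.
#' @export
summarize_hd <- function(regions) {
  if (!nrow(regions))
    return(data.frame(what = character(), n = integer(), min = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      max = numeric()))
  five <- function(x) {
    q <- quantile(x, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
    data.frame(n = length(x), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  }
  totals <- tapply(regions$length, regions$sample, sum)
  out <- rbind(cbind(what = "region_length", five(regions$length)),
               cbind(what = "per_genome_total", five(as.numeric(totals))))
  rownames(out) <- NULL
  out
}
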