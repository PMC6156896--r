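## Methylation arm: 3-state beta-mixture EM, probe-type normalization that
## maps the type-II state distributions onto their type-I counterparts
## (beta-mixture quantile normalization), M-value transform, and the
## post-minus-pre methylation response.

#' Fit a beta mixture by EM
#'
#' Deterministic initialization by value tertiles; the M-step maximizes each
#' component's weighted beta log-likelihood numerically (generalized EM), so
#' the log-likelihood trace is non-decreasing. States are labeled by
#' ascending mean. A component collapsing below weight `1e-4` triggers a
#' flagged refit with one state fewer.
#'
#' @param x beta values in (0, 1), at least 100 of them.
#' @param n_states number of components (default 3).
#' @param tol log-likelihood convergence gain (default 1e-6).
#' @param maxit maximum EM iterations (default 500).
#' @return list with `shapes` (n_states x 2), `weights`, `means`,
#'   `posterior` (n x n_states), `loglik` (trace), `iterations`,
#'   `n_states`, `degenerate` (TRUE when the refit path was taken).
#' @export
fit_beta_mixture <- function(x, n_states = 3L, tol = 1e-6, maxit = 500L) {
  x <- x[!is.na(x)]
  if (length(x) < 100L) stopf("need at least 100 beta values, got %d", length(x))
  if (any(x <= 0 | x >= 1)) stopf("beta values must lie strictly in (0,1)")
  n <- length(x)

  mom_shapes <- function(v) {
    m <- mean(v); s2 <- max(var(v), 1e-6)
    s2 <- min(s2, m * (1 - m) * 0.99)
    a <- m * (m * (1 - m) / s2 - 1)
    b <- (1 - m) * (m * (1 - m) / s2 - 1)
    clamp(c(a, b), 0.05, 1e4)
  }
  ## deterministic quantile-slab initialization
  br <- quantile(x, probs = seq(0, 1, length.out = n_states + 1L))
  grp <- cut(x, breaks = unique(br), include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < n_states) grp <- rep(seq_len(n_states), length.out = n)
  shapes <- t(vapply(seq_len(n_states), function(k) mom_shapes(x[grp == k]),
                     numeric(2)))
  weights <- as.vector(table(factor(grp, levels = seq_len(n_states)))) / n
  weights <- pmax(weights, 1e-3); weights <- weights / sum(weights)

  ## Weighted beta MLE through sufficient statistics: the component
  ## log-likelihood is (a-1)*T1 + (b-1)*T2 - W*lbeta(a,b) with
  ## T1 = sum(w log x), T2 = sum(w log(1-x)), W = sum(w) -- O(1) per
  ## evaluation, so the M-step is exact and cheap.
  lx <- log(x); l1x <- log1p(-x)
  mle_shapes <- function(start, wts) {
    T1 <- sum(wts * lx); T2 <- sum(wts * l1x); W <- sum(wts)
    nll <- function(par) {
      a <- exp(par[1]); b <- exp(par[2])
      -((a - 1) * T1 + (b - 1) * T2 - W * lbeta(a, b))
    }
    grad <- function(par) {
      a <- exp(par[1]); b <- exp(par[2])
      dab <- digamma(a + b)
      -c(a * (T1 - W * (digamma(a) - dab)),
         b * (T2 - W * (digamma(b) - dab)))
    }
    opt <- optim(log(start), nll, grad, method = "BFGS",
                 control = list(maxit = 100, reltol = 1e-12))
    if (opt$value > nll(log(start)) + 1e-12) start else exp(opt$par)
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  post <- NULL
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(n_states), function(k)
      weights[k] * dbeta(x, shapes[k, 1], shapes[k, 2]), numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    post <- dens / tot
    if (ll - ll_old < tol || it >= maxit) break
    ll_old <- ll
    weights <- colMeans(post)
    for (k in seq_len(n_states)) {
      if (weights[k] < 1e-8) next
      shapes[k, ] <- clamp(mle_shapes(shapes[k, ], post[, k]), 1e-3, 1e6)
    }
  }
  ## Degenerate fits: a collapsed weight, or two states landing on top of
  ## each other (misspecified state count) -> refit with one state fewer.
  means_raw <- shapes[, 1] / rowSums(shapes)
  if (n_states > 1L &&
      (any(weights < 1e-4) || min(diff(sort(means_raw))) < 0.1)) {
    out <- fit_beta_mixture(x, n_states - 1L, tol = tol, maxit = maxit)
    out$degenerate <- TRUE
    return(out)
  }
  means <- shapes[, 1] / rowSums(shapes)
  o <- order(means)
  list(shapes = shapes[o, , drop = FALSE], weights = weights[o],
       means = means[o], posterior = post[, o, drop = FALSE],
       loglik = ll_trace, iterations = it, n_states = n_states,
       degenerate = FALSE)
}

## Piecewise monotone map of one sample's type-II betas onto the type-I state
## distributions. Outer states map by probability integral transform through
## the fitted components; the intermediate stretch is a monotone affine
## bridge between the two transformed boundaries.
bmiq_map_sample <- function(xII, fitI, fitII, eps = 1e-6) {
  kU <- 1L; kM <- fitII$n_states
  cls <- max.col(fitII$posterior)
  tU <- if (any(cls == kU)) max(xII[cls == kU]) else quantile(xII, 1 / 3, names = FALSE)
  tM <- if (any(cls == kM)) min(xII[cls == kM]) else quantile(xII, 2 / 3, names = FALSE)
  if (tU >= tM) { tU <- min(tU, tM); tM <- tU }
  kUI <- 1L; kMI <- fitI$n_states
  mapU <- function(v) qbeta(pbeta(v, fitII$shapes[kU, 1], fitII$shapes[kU, 2]),
                            fitI$shapes[kUI, 1], fitI$shapes[kUI, 2])
  mapM <- function(v) qbeta(pbeta(v, fitII$shapes[kM, 1], fitII$shapes[kM, 2]),
                            fitI$shapes[kMI, 1], fitI$shapes[kMI, 2])
  y <- numeric(length(xII))
  lo <- xII <= tU
  hi <- xII >= tM
  mid <- !lo & !hi
  y[lo] <- mapU(xII[lo])
  y[hi] <- mapM(xII[hi])
  if (any(mid)) {
    yU <- mapU(tU); yM <- mapM(tM)
    if (yM < yU) { yM <- yU }                    # keep the bridge monotone
    if (tM > tU) {
      y[mid] <- yU + (xII[mid] - tU) * (yM - yU) / (tM - tU)
    } else y[mid] <- yU
  }
  clamp(y, eps, 1 - eps)
}

#' Beta-mixture quantile normalization of type-II probes
#'
#' Per sample and visit: fits 3-state beta mixtures to the type-I and
#' type-II beta distributions, then maps type-II values onto the type-I
#' scale — unmethylated and methylated states by quantile transformation
#' through the fitted components, the intermediate stretch by a monotone
#' affine bridge. Type-I probes pass through untouched; within-type rank
#' order is preserved. A sample whose mixture fit fails is passed through
#' unnormalized with a warning.
#'
#' @param meth a [methylation_set()] with both probe types.
#' @return the normalized [methylation_set()] with a `bmiq` diagnostics
#'   attribute (per visit/sample: iterations, final log-likelihood, flags).
#' @export
bmiq_normalize <- function(meth) {
  stopifnot(inherits(meth, "methylation_set"))
  tI <- meth$annot$type == "I"
  tII <- meth$annot$type == "II"
  if (!any(tI) || !any(tII)) stopf("both probe types are required")
  diag_rows <- list()
  for (v in names(meth$beta)) {
    B <- meth$beta[[v]]
    for (s in seq_len(ncol(B))) {
      res <- tryCatch({
        fitI <- fit_beta_mixture(B[tI, s])
        fitII <- fit_beta_mixture(B[tII, s])
        B[tII, s] <- bmiq_map_sample(B[tII, s], fitI, fitII, eps = meth$eps)
        data.frame(visit = v, sample = colnames(B)[s] %||% s,
                   ok = TRUE, degenerate = fitI$degenerate || fitII$degenerate,
                   iter_I = fitI$iterations, iter_II = fitII$iterations,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warnf("BMIQ fit failed for sample %s (%s); passed through unnormalized",
              colnames(B)[s] %||% s, conditionMessage(e))
        data.frame(visit = v, sample = colnames(B)[s] %||% s, ok = FALSE,
                   degenerate = NA, iter_I = NA, iter_II = NA,
                   stringsAsFactors = FALSE)
      })
      diag_rows[[length(diag_rows) + 1L]] <- res
    }
    meth$beta[[v]] <- B
  }
  attr(meth, "bmiq") <- do.call(rbind, diag_rows)
  meth
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`; strictly increasing with inverse
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param beta values strictly inside (0, 1) (clamp first, see
#'   [methylation_set()]).
#' @return M values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stopf("beta values must lie strictly in (0,1); clamp first")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M values.
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Methylation response to treatment
#'
#' Element-wise M-value change, visit 4 minus visit 2; missing where either
#' visit is missing.
#'
#' @param meth a (normalized) [methylation_set()] with visits `v2` and `v4`.
#' @return CpG x sample matrix of M-value changes.
#' @export
methylation_response <- function(meth) {
  stopifnot(all(c("v2", "v4") %in% names(meth$beta)))
  beta_to_m(meth$beta$v4) - beta_to_m(meth$beta$v2)
}
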