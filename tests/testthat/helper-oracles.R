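# Independent oracles and tiny fixture builders shared across tests. Oracles
# deliberately take the most literal computational route (explicit normal
# equations, exhaustive scans) rather than the package's code paths.

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Weighted least squares fitted value at u = 0 by explicit normal equations.
oracle_wls_at0 <- function(u, x, w, degree = 1) {
  X <- outer(u, 0:degree, `^`)
  W <- diag(w, length(w))
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% x)
  beta[1, 1]
}

# OLS with HC0 (heteroskedasticity-robust) sandwich covariance.
oracle_hc0 <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  r <- drop(y - X %*% beta)
  meat <- t(X) %*% diag(r^2) %*% X
  V <- XtXi %*% meat %*% XtXi
  list(beta = drop(beta), se = sqrt(diag(V)))
}

# Exhaustive run-scan over a toy intensity vector: returns (start_idx, end_idx)
# of maximal runs >= thr.
oracle_runs <- function(h, thr) {
  runs <- list()
  i <- 1
  while (i <= length(h)) {
    if (!is.na(h[i]) && h[i] >= thr) {
      j <- i
      while (j < length(h) && !is.na(h[j + 1]) && h[j + 1] >= thr) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Type-7 sample quantile by the textbook interpolation formula.
oracle_q7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Small genotype fixture: explicit codes on two chromosomes.
make_gm <- function(geno, pos = NULL, chrom = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep("1", m)
  genotype_matrix(geno,
                  data.frame(id = paste0("s", seq_len(m)), chrom = chrom,
                             pos = pos, a1 = "A", a2 = "C"),
                  samples = paste0("I", seq_len(nrow(geno))),
                  pedigree = paste0("P", seq_len(nrow(geno))))
}

# Hand-built intensity profile over explicit anchors (one chromosome unless
# chrom given); H is samples x windows.
make_profile <- function(H, anchors, chrom = NULL) {
  H <- rbind(H)
  nw <- ncol(H)
  if (is.null(chrom)) chrom <- rep("1", nw)
  snp_map <- data.frame(id = paste0("s", seq_len(nw)), chrom = chrom,
                        pos = anchors)
  ws <- structure(list(windows = data.frame(
    window = seq_len(nw), chrom = chrom, anchor = seq_len(nw),
    anchor_id = snp_map$id, anchor_pos = anchors,
    first = seq_len(nw), last = seq_len(nw), k = 1L),
    snp_map = snp_map, fraction = NA), class = "window_set")
  rownames(H) <- paste0("I", seq_len(nrow(H)))
  structure(list(H = H, windows = ws, weights = rep(1, nw), degree = 0L),
            class = "intensity_profile")
}

# Small simulated cohort used by several association tests.
small_cohort <- function(seed = 1, n_families = 30, snps = 300, beta_hd = -40,
                         ...) {
  cfg <- sim_config(n_families = n_families, n_chromosomes = 1L,
                    snps_per_chromosome = snps, chromosome_length_bp = 6e7,
                    tg_model = list(beta_hd = beta_hd, ...), seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g$genotypes, g$truth, cfg)
  list(cfg = cfg, g = g, pheno = ph)
}
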