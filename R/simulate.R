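## Synthetic cohort generator: multi-generation pedigrees, gene-dropped SNP
## genotypes with planted runs of homozygosity, a treatment-response phenotype
## with family correlation and a planted window-level effect, and two-probe-
## type methylation with a planted cis link. Test scaffolding for the
## pipeline; none of it claims to be a generative model of the real cohort.

#' Simulation configuration
#'
#' Defaults give a desk-scale cohort (about 60 families of ~5 members, two
#' chromosomes of 2,000 SNPs over 60 Mb each) on which the full pipeline runs
#' in minutes.
#'
#' @param n_families number of independent pedigrees.
#' @param n_children_range inclusive range for children per founder couple.
#' @param p_third_generation probability a family gains a married-in founder
#'   and grandchildren.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp genome shape.
#' @param maf_range alternate-allele frequency range (uniform draw).
#' @param roh_plan data frame of planted homozygous segments with columns
#'   `chrom`, `carrier_frac`, `length_bp`, `intensity` (fraction of segment
#'   SNPs forced homozygous) and optional `start`; default plants one 10 Mb
#'   fully homozygous segment on chromosome 1 in 10% of samples. The first
#'   row is the "effect" segment that drives the phenotype and cis links.
#'   `NULL` plants nothing.
#' @param effect_span_bp width of the window, centered in the effect segment,
#'   over which the "true window intensity" driving the phenotype is measured
#'   (default 3 Mb, the span of a default-fraction sliding window). A
#'   window-level effect is defined at window scale; tying the truth to the
#'   whole segment would make a window-based estimate biased by construction.
#' @param tg_model list: `beta_hd` (TG response change per unit true window
#'   intensity, mg/dL), `intercept`, `b_sex`, `b_age`, `b_center`,
#'   `b_smoking`, `b_index`, `family_sd`, `resid_sd`, `visit_sd`,
#'   `baseline_meanlog`, `baseline_sdlog`, `p_missing_post`.
#' @param meth_model list: `n_cpg`, `frac_type2`, `state_weights` (3 mixture
#'   weights), `state_shapes` (3 x 2 beta shape matrix), `compression`
#'   (type-II logit compression factor, 1 = no bias), `cis_n`, `cis_effect`
#'   (M-value change per unit intensity at visit 4), `noise_sd` (visit-4 M
#'   noise).
#' @param seed integer seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 60L,
                       n_children_range = c(2L, 4L),
                       p_third_generation = 0.4,
                       n_chromosomes = 2L,
                       snps_per_chromosome = 2000L,
                       chromosome_length_bp = 6e7,
                       maf_range = c(0.01, 0.5),
                       roh_plan = NULL,
                       effect_span_bp = 3e6,
                       tg_model = list(),
                       meth_model = list(),
                       seed = 1L) {
  if (is.null(roh_plan))
    roh_plan <- data.frame(chrom = "1", carrier_frac = 0.1,
                           length_bp = 1e7, intensity = 1)
  tg_defaults <- list(beta_hd = -40, intercept = -30, b_sex = 5, b_age = 0.2,
                      b_center = 8, b_smoking = 6, b_index = 10,
                      family_sd = 20, resid_sd = 30, visit_sd = 5,
                      baseline_meanlog = log(180), baseline_sdlog = 0.3,
                      p_missing_post = 0.05)
  meth_defaults <- list(n_cpg = 2000L, frac_type2 = 0.7,
                        state_weights = c(0.45, 0.10, 0.45),
                        state_shapes = rbind(c(2, 20), c(5, 5), c(20, 2)),
                        compression = 0.7, cis_n = 5L, cis_effect = 1,
                        noise_sd = 0.2)
  cfg <- list(n_families = as.integer(n_families),
              n_children_range = as.integer(n_children_range),
              p_third_generation = p_third_generation,
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_bp = chromosome_length_bp,
              maf_range = maf_range,
              roh_plan = as.data.frame(roh_plan),
              effect_span_bp = effect_span_bp,
              tg_model = modifyList(tg_defaults, tg_model),
              meth_model = modifyList(meth_defaults, meth_model),
              seed = as.integer(seed))
  stopifnot(all(cfg$roh_plan$carrier_frac >= 0 & cfg$roh_plan$carrier_frac <= 1),
            all(cfg$roh_plan$length_bp > 0),
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5)
  if (abs(sum(cfg$meth_model$state_weights) - 1) > 1e-8)
    stopf("methylation state weights must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

## Pedigree table: founders (generation 1), their children, optionally a
## married-in founder and grandchildren.
simulate_pedigree_table <- function(config) {
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%03d", f)
    nm <- function(i) sprintf("%s_I%02d", fam, i)
    i <- 0L
    add <- function(father, mother, gen) {
      i <<- i + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = nm(i), pedigree = fam, father = father, mother = mother,
        generation = gen, stringsAsFactors = FALSE)
      nm(i)
    }
    fa <- add(NA, NA, 1L); mo <- add(NA, NA, 1L)
    nk <- sample(seq(config$n_children_range[1], config$n_children_range[2]), 1L)
    kids <- vapply(seq_len(nk), function(k) add(fa, mo, 2L), "")
    if (runif(1) < config$p_third_generation) {
      spouse <- add(NA, NA, 2L)
      ngk <- sample(1:2, 1L)
      for (g in seq_len(ngk)) add(kids[1L], spouse, 3L)
    }
  }
  do.call(rbind, rows)
}

#' Simulate genotypes by Mendelian gene dropping
#'
#' Founder haplotypes are drawn per SNP as Bernoulli(alternate-allele
#' frequency); each non-founder inherits one randomly chosen allele per SNP
#' from each parent (SNPs are unlinked). Planted homozygous segments then
#' overwrite carrier genotypes with the homozygote of the more frequent
#' allele over the segment.
#'
#' @param config a [sim_config()].
#' @param track_origin keep founder-allele origin labels (for small fixtures;
#'   memory grows with samples x SNPs).
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (planted
#'   segments, effect region, per-sample true intensity over the effect
#'   region, allele frequencies, pedigree table, seed).
#' @export
simulate_genotypes <- function(config, track_origin = FALSE) {
  set.seed(derive_seed(config$seed, "genotypes"))
  ped <- simulate_pedigree_table(config)
  n <- nrow(ped)
  n_chr <- config$n_chromosomes
  m_chr <- config$snps_per_chromosome
  m <- n_chr * m_chr
  pos <- unlist(lapply(seq_len(n_chr), function(ch)
    sort(sample.int(config$chromosome_length_bp, m_chr))))
  snp_map <- data.frame(
    id = sprintf("snp%d_%d", rep(seq_len(n_chr), each = m_chr),
                 rep(seq_len(m_chr), n_chr)),
    chrom = as.character(rep(seq_len(n_chr), each = m_chr)),
    pos = pos, a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  freq <- runif(m, config$maf_range[1], config$maf_range[2])

  hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
  org1 <- if (track_origin) matrix(NA_integer_, n, m) else NULL
  org2 <- if (track_origin) matrix(NA_integer_, n, m) else NULL
  founder_label <- 0L
  idx_of <- setNames(seq_len(n), ped$sample)
  for (i in seq_len(n)) {
    if (is.na(ped$father[i])) {
      hap1[i, ] <- rbinom(m, 1L, freq)
      hap2[i, ] <- rbinom(m, 1L, freq)
      if (track_origin) {
        org1[i, ] <- founder_label + 1L
        org2[i, ] <- founder_label + 2L
        founder_label <- founder_label + 2L
      }
    } else {
      fi <- idx_of[[ped$father[i]]]; mi <- idx_of[[ped$mother[i]]]
      pick_f <- runif(m) < 0.5
      pick_m <- runif(m) < 0.5
      hap1[i, ] <- ifelse(pick_f, hap1[fi, ], hap2[fi, ])
      hap2[i, ] <- ifelse(pick_m, hap1[mi, ], hap2[mi, ])
      if (track_origin) {
        org1[i, ] <- ifelse(pick_f, org1[fi, ], org2[fi, ])
        org2[i, ] <- ifelse(pick_m, org1[mi, ], org2[mi, ])
      }
    }
  }

  ## Plant homozygous segments.
  plan <- config$roh_plan
  segments <- list()
  for (r in seq_len(nrow(plan))) {
    if (plan$carrier_frac[r] <= 0) next
    ch <- as.character(plan$chrom[r])
    len <- plan$length_bp[r]
    if (len > config$chromosome_length_bp)
      stopf("planted segment (%g bp) exceeds chromosome length", len)
    start <- if ("start" %in% names(plan) && !is.na(plan$start[r])) plan$start[r]
             else round((config$chromosome_length_bp - len) / 2)
    end <- start + len - 1
    in_seg <- which(snp_map$chrom == ch & snp_map$pos >= start & snp_map$pos <= end)
    carriers <- sort(sample.int(n, round(plan$carrier_frac[r] * n)))
    hom_allele <- ifelse(freq[in_seg] > 0.5, 1L, 0L)
    for (s in carriers) {
      force <- in_seg[runif(length(in_seg)) < plan$intensity[r]]
      fa <- hom_allele[match(force, in_seg)]
      hap1[s, force] <- fa; hap2[s, force] <- fa
      segments[[length(segments) + 1L]] <- data.frame(
        sample = ped$sample[s], chrom = ch, start = start, end = end,
        stringsAsFactors = FALSE)
    }
  }
  geno <- hap1 + hap2
  gm <- genotype_matrix(geno, snp_map, ped$sample, ped$pedigree)

  ## Effect region (first plan row) and per-sample true intensity: the raw
  ## homozygosity proportion over the segment's SNPs.
  truth <- list(segments = if (length(segments)) do.call(rbind, segments)
                           else data.frame(),
                pedigree = ped, freq = freq, seed = config$seed)
  if (nrow(plan) && plan$carrier_frac[1] > 0 && nrow(truth$segments) > 0) {
    first <- truth$segments[!duplicated(truth$segments[c("chrom", "start")]), ][1, ]
    mid <- (first$start + first$end) / 2
    span <- min(config$effect_span_bp, first$end - first$start + 1)
    w_start <- max(first$start, round(mid - span / 2))
    w_end <- min(first$end, round(mid + span / 2))
    in_eff <- which(snp_map$chrom == first$chrom &
                    snp_map$pos >= w_start & snp_map$pos <= w_end)
    if (!length(in_eff)) {       # sparse maps: fall back to the whole segment
      w_start <- first$start; w_end <- first$end
      in_eff <- which(snp_map$chrom == first$chrom &
                      snp_map$pos >= w_start & snp_map$pos <= w_end)
    }
    ind <- homozygosity_indicator(gm)[, in_eff, drop = FALSE]
    ## true window intensity = tricube-weighted homozygosity over the effect
    ## window (the planted effect is a window-level dose, and window
    ## intensity in this model is kernel-weighted local homozygosity)
    u_eff <- (snp_map$pos[in_eff] - (w_start + w_end) / 2) /
      max((w_end - w_start) / 2, 1)
    k_eff <- (1 - pmin(abs(u_eff), 1)^3)^3
    if (sum(k_eff) > 0) {
      ind <- sweep(ind, 2, k_eff / sum(k_eff), `*`)
      ind <- ind * length(in_eff)      # keep rowMeans = weighted mean
    }
    truth$effect_region <- data.frame(chrom = first$chrom, start = first$start,
                                      end = first$end)
    truth$effect_window <- data.frame(chrom = first$chrom, start = w_start,
                                      end = w_end)
    truth$true_intensity <- rowMeans(ind, na.rm = TRUE)
    truth$beta_hd <- config$tg_model$beta_hd
  }
  if (track_origin) truth$origin <- list(org1, org2)
  list(genotypes = gm, truth = truth)
}

#' Simulate TG-response phenotypes
#'
#' The treatment effect per sample is
#' `delta = intercept + beta_hd * true_intensity + covariate terms +
#' family effect + residual`; pre-treatment visits are baseline TG plus visit
#' noise and post-treatment visits add `delta`, so
#' `mean(V3, V4) - mean(V1, V2) = delta + visit-noise contrast`.
#'
#' @param gm a [genotype_matrix()] from [simulate_genotypes()].
#' @param truth matching truth list (supplies the true window intensity).
#' @param config the same [sim_config()].
#' @return a [phenotype_table()].
#' @export
simulate_phenotypes <- function(gm, truth, config) {
  set.seed(derive_seed(config$seed, "phenotypes"))
  tm <- config$tg_model
  ped <- truth$pedigree
  n <- nrow(ped)
  if (is.null(truth$true_intensity)) {
    if (!is.null(config$roh_plan) && nrow(config$roh_plan) &&
        any(config$roh_plan$carrier_frac > 0) && tm$beta_hd != 0)
      stopf("truth lacks the effect-window intensity")
    ti <- rep(0, n)
  } else ti <- truth$true_intensity
  sex <- rbinom(n, 1, 0.5)
  age <- rnorm(n, c(62, 38, 18)[ped$generation], c(8, 8, 4)[ped$generation])
  age <- clamp(age, 16, 90)
  fam_center <- setNames(sample(c("Utah", "Minnesota"), config$n_families,
                                replace = TRUE),
                         unique(ped$pedigree))
  center <- unname(fam_center[ped$pedigree])
  smoking <- rbinom(n, 1, 0.2)
  atp <- rbinom(n, 1, 0.35)
  idf <- rbinom(n, 1, 0.4)
  fam_eff <- setNames(rnorm(config$n_families, 0, tm$family_sd),
                      unique(ped$pedigree))
  delta <- tm$intercept + tm$beta_hd * ti + tm$b_sex * sex +
    tm$b_age * (age - 50) + tm$b_center * (center == "Utah") +
    tm$b_smoking * smoking + tm$b_index * atp +
    unname(fam_eff[ped$pedigree]) + rnorm(n, 0, tm$resid_sd)
  baseline <- exp(rnorm(n, tm$baseline_meanlog, tm$baseline_sdlog))
  tg <- sapply(1:4, function(v)
    baseline + (v >= 3) * delta + rnorm(n, 0, tm$visit_sd))
  tg <- pmax(tg, 0)
  for (v in 3:4) {
    miss <- runif(n) < tm$p_missing_post
    tg[miss, v] <- NA_real_
  }
  phenotype_table(data.frame(
    sample = ped$sample, pedigree = ped$pedigree,
    tg1 = tg[, 1], tg2 = tg[, 2], tg3 = tg[, 3], tg4 = tg[, 4],
    sex = sex, age = age, center = center, smoking = smoking,
    atp = atp, idf = idf, stringsAsFactors = FALSE))
}

logit2 <- function(b) log2(b / (1 - b))
expit2 <- function(m) 2^m / (1 + 2^m)

#' Simulate two-probe-type methylation data at two visits
#'
#' Each CpG gets a methylation state (unmethylated / hemimethylated /
#' methylated) and a probe type. Visit-2 betas are drawn from the state's
#' beta distribution; visit-4 M values add noise plus, for cis-linked CpGs
#' (placed inside the effect region), `cis_effect * true_intensity`. Type-II
#' probes are then compressed toward beta 0.5 by scaling the M value with the
#' compression factor, mimicking the reduced type-II dynamic range that
#' beta-mixture quantile normalization corrects.
#'
#' @param gm a [genotype_matrix()] (supplies samples and chromosome layout).
#' @param truth truth list from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `meth` (a [methylation_set()]) and `truth` additions
#'   (`cis_cpgs`, `cis_effect`).
#' @export
simulate_methylation <- function(gm, truth, config) {
  set.seed(derive_seed(config$seed, "methylation"))
  mm <- config$meth_model
  if (abs(sum(mm$state_weights) - 1) > 1e-8)
    stopf("methylation state weights must sum to 1")
  n <- length(gm$samples)
  n_cpg <- mm$n_cpg
  chroms <- unique(gm$snp_map$chrom)
  chrom <- sample(chroms, n_cpg, replace = TRUE)
  pos <- sample.int(config$chromosome_length_bp, n_cpg, replace = TRUE)
  ## cis CpGs live inside the effect window (the span whose intensity drives
  ## the planted signal), so a window-span cis definition finds them
  cis_idx <- integer(0)
  er <- truth$effect_window %||% truth$effect_region
  if (!is.null(er) && mm$cis_n > 0) {
    ## central third of the effect window, so any window anchored near the
    ## planted signal (plus the default cis margin) covers them
    mid <- (er$start + er$end) / 2
    third <- (er$end - er$start) / 6
    cis_idx <- seq_len(mm$cis_n)
    chrom[cis_idx] <- er$chrom
    pos[cis_idx] <- if (mm$cis_n == 1L) round(mid) else
      round(seq(mid - third, mid + third, length.out = mm$cis_n))
  }
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  cis_idx <- match(cis_idx, o)
  type <- ifelse(runif(n_cpg) < mm$frac_type2, "II", "I")
  state <- sample.int(3L, n_cpg, replace = TRUE, prob = mm$state_weights)
  annot <- data.frame(cpg = sprintf("cg%06d", seq_len(n_cpg)),
                      chrom = chrom, pos = pos, type = type,
                      stringsAsFactors = FALSE)
  sh <- mm$state_shapes
  beta2 <- matrix(rbeta(n_cpg * n, sh[state, 1], sh[state, 2]),
                  n_cpg, n)
  eps <- 1e-6
  beta2 <- clamp(beta2, eps, 1 - eps)
  m2 <- logit2(beta2)
  m4 <- m2 + matrix(rnorm(n_cpg * n, 0, mm$noise_sd), n_cpg, n)
  if (length(cis_idx) && !is.null(truth$true_intensity))
    m4[cis_idx, ] <- m4[cis_idx, ] +
      mm$cis_effect * rep(truth$true_intensity, each = length(cis_idx))
  ## type-II dynamic-range compression on the M scale
  ii <- type == "II"
  m2[ii, ] <- m2[ii, ] * mm$compression
  m4[ii, ] <- m4[ii, ] * mm$compression
  beta <- list(v2 = expit2(m2), v4 = expit2(m4))
  for (v in names(beta)) {
    colnames(beta[[v]]) <- gm$samples
    rownames(beta[[v]]) <- annot$cpg
  }
  meth <- methylation_set(beta, annot, eps = eps)
  list(meth = meth,
       cis_cpgs = annot$cpg[cis_idx],
       cis_effect = mm$cis_effect)
}
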