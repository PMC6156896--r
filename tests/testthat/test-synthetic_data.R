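test_that("generators are deterministic and respect a zero carrier fraction", {
  cfg <- sim_config(n_families = 5, n_chromosomes = 1L,
                    snps_per_chromosome = 100,
                    roh_plan = data.frame(chrom = "1", carrier_frac = 0,
                                          length_bp = 1e7, intensity = 1),
                    seed = 3)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$genotypes$genotypes, g2$genotypes$genotypes)
  expect_equal(nrow(g1$truth$segments), 0)
  ph1 <- simulate_phenotypes(g1$genotypes, g1$truth, cfg)
  ph2 <- simulate_phenotypes(g2$genotypes, g2$truth, cfg)
  expect_identical(ph1, ph2)
  m1 <- simulate_methylation(g1$genotypes, g1$truth, cfg)
  m2 <- simulate_methylation(g2$genotypes, g2$truth, cfg)
  expect_identical(m1$meth$beta, m2$meth$beta)
})

test_that("pooled sample allele frequency matches the binomial draw", {
  # all SNPs at frequency 0.3; pooled MAF within 0.29-0.31 (~3 SE)
  cfg <- sim_config(n_families = 90, n_chromosomes = 1L,
                    snps_per_chromosome = 1500, maf_range = c(0.3, 0.3),
                    roh_plan = data.frame(chrom = "1", carrier_frac = 0,
                                          length_bp = 1e6, intensity = 1),
                    seed = 5)
  g <- simulate_genotypes(cfg)
  maf <- snp_maf(g$genotypes)
  expect_gt(mean(maf), 0.29)
  expect_lt(mean(maf), 0.31)
})

test_that("gene dropping conserves founder allele identity", {
  cfg <- sim_config(n_families = 4, n_chromosomes = 1L,
                    snps_per_chromosome = 60, p_third_generation = 1,
                    roh_plan = data.frame(chrom = "1", carrier_frac = 0,
                                          length_bp = 1e6, intensity = 1),
                    seed = 9)
  g <- simulate_genotypes(cfg, track_origin = TRUE)
  ped <- g$truth$pedigree
  org <- g$truth$origin
  # reconstruct each founder haplotype by its origin label
  founders <- which(is.na(ped$father))
  hap_by_label <- list()
  gm <- g$genotypes$genotypes
  # founder rows carry constant labels; recover their haplotypes from truth
  for (i in founders) {
    l1 <- unique(org[[1]][i, ]); l2 <- unique(org[[2]][i, ])
    expect_length(l1, 1); expect_length(l2, 1)
  }
  # every offspring allele label must occur among its parents' labels
  for (i in which(!is.na(ped$father))) {
    fi <- match(ped$father[i], ped$sample)
    mi <- match(ped$mother[i], ped$sample)
    parent_labels_f <- unique(c(org[[1]][fi, ], org[[2]][fi, ]))
    parent_labels_m <- unique(c(org[[1]][mi, ], org[[2]][mi, ]))
    expect_true(all(org[[1]][i, ] %in% parent_labels_f))
    expect_true(all(org[[2]][i, ] %in% parent_labels_m))
  }
})

test_that("planted segments are truly homozygous in carriers", {
  cfg <- sim_config(n_families = 10, n_chromosomes = 1L,
                    snps_per_chromosome = 300, seed = 2)
  g <- simulate_genotypes(cfg)
  seg <- g$truth$segments
  expect_gt(nrow(seg), 0)
  sm <- g$genotypes$snp_map
  for (r in seq_len(nrow(seg))) {
    idx <- which(sm$chrom == seg$chrom[r] & sm$pos >= seg$start[r] &
                   sm$pos <= seg$end[r])
    codes <- g$genotypes$genotypes[match(seg$sample[r], g$genotypes$samples), idx]
    expect_equal(sum(codes == 1L, na.rm = TRUE), 0)
  }
  # segments lie within chromosome bounds
  expect_true(all(seg$start >= 1 & seg$end <= cfg$chromosome_length_bp))
  # oversized segment is rejected
  bad <- sim_config(n_chromosomes = 1L, snps_per_chromosome = 100,
                    roh_plan = data.frame(chrom = "1", carrier_frac = 0.1,
                                          length_bp = 7e7, intensity = 1),
                    seed = 1)
  expect_error(simulate_genotypes(bad), "exceeds chromosome length")
})

test_that("null phenotype model yields null slope coverage", {
  # beta_hd = 0: the 95% CI of the slope of response on true intensity covers
  # 0 in >= 90% of replicates
  cover <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_families = 140, n_chromosomes = 1L,
                      snps_per_chromosome = 60, chromosome_length_bp = 6e7,
                      tg_model = list(beta_hd = 0, p_missing_post = 0),
                      seed = 1000 + r)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g$genotypes, g$truth, cfg)
    y <- tg_response(ph)
    fit <- summary(lm(y ~ g$truth$true_intensity))$coefficients
    ci <- fit[2, 1] + c(-1.96, 1.96) * fit[2, 2]
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1L
  }
  expect_gte(cover, 90L)
})

test_that("noiseless phenotype model is exact after covariate adjustment", {
  cfg <- sim_config(n_families = 20, n_chromosomes = 1L,
                    snps_per_chromosome = 200,
                    tg_model = list(beta_hd = -30, family_sd = 0,
                                    resid_sd = 0, visit_sd = 0,
                                    p_missing_post = 0),
                    seed = 4)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g$genotypes, g$truth, cfg)
  y <- tg_response(ph)
  ti <- g$truth$true_intensity
  fit <- lm(y ~ ti + ph$sex + ph$age + factor(ph$center) + ph$smoking + ph$atp)
  expect_equal(unname(coef(fit)["ti"]), -30, tolerance = 1e-8)
})

test_that("family random effect with zero residual gives zero within-family variance", {
  cfg <- sim_config(n_families = 25, n_chromosomes = 1L,
                    snps_per_chromosome = 100,
                    roh_plan = data.frame(chrom = "1", carrier_frac = 0,
                                          length_bp = 1e6, intensity = 1),
                    tg_model = list(beta_hd = 0, family_sd = 20, resid_sd = 0,
                                    visit_sd = 0, b_sex = 0, b_age = 0,
                                    b_center = 0, b_smoking = 0, b_index = 0,
                                    p_missing_post = 0),
                    seed = 6)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g$genotypes, g$truth, cfg)
  y <- tg_response(ph)
  wfv <- tapply(y, ph$pedigree, var)
  expect_true(all(wfv[!is.na(wfv)] < 1e-18))
  expect_gt(var(tapply(y, ph$pedigree, mean)), 1)   # between-family spread
})

test_that("probe-type compression and mixture states behave as declared", {
  # compression 1 -> type-I and type-II marginals agree (KS p > 0.01)
  cfg <- sim_config(n_families = 2, n_chromosomes = 1L,
                    snps_per_chromosome = 100,
                    meth_model = list(n_cpg = 10000L, frac_type2 = 0.5,
                                      compression = 1, cis_n = 0L),
                    seed = 8)
  g <- simulate_genotypes(cfg)
  me <- simulate_methylation(g$genotypes, g$truth, cfg)
  b <- me$meth$beta$v2[, 1]
  ks <- suppressWarnings(
    stats::ks.test(b[me$meth$annot$type == "I"], b[me$meth$annot$type == "II"]))
  expect_gt(ks$p.value, 0.01)

  # state weights (1,0,0): everything from the unmethylated component
  cfg2 <- sim_config(n_families = 2, n_chromosomes = 1L,
                     snps_per_chromosome = 100,
                     meth_model = list(n_cpg = 3000L, frac_type2 = 0,
                                       state_weights = c(1, 0, 0), cis_n = 0L),
                     seed = 8)
  g2 <- simulate_genotypes(cfg2)
  me2 <- simulate_methylation(g2$genotypes, g2$truth, cfg2)
  expect_lt(mean(me2$meth$beta$v2), 0.15)      # Beta(2,20) mean = 1/11
  expect_lt(max(me2$meth$beta$v2), 0.9)

  # cis effect 0: no intensity association at the cis CpGs by construction
  cfg3 <- sim_config(n_families = 40, n_chromosomes = 1L,
                     snps_per_chromosome = 100,
                     meth_model = list(n_cpg = 200L, cis_n = 3L,
                                       cis_effect = 0),
                     seed = 8)
  g3 <- simulate_genotypes(cfg3)
  me3 <- simulate_methylation(g3$genotypes, g3$truth, cfg3)
  m <- beta_to_m(me3$meth$beta$v4) - beta_to_m(me3$meth$beta$v2)
  r <- cor(m[me3$cis_cpgs[1], ], g3$truth$true_intensity)
  expect_lt(abs(r), 0.2)
})
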