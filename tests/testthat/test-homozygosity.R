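test_that("window construction follows the 5% nearest-neighbor rule", {
  sm <- data.frame(id = paste0("s", 1:100), chrom = "1", pos = 1:100 * 1e4)
  ws <- build_windows(sm, 0.05)
  expect_equal(nrow(ws$windows), 100)               # one window per SNP
  expect_true(all(ws$windows$k == 5))
  expect_true(all(ws$windows$last - ws$windows$first + 1L == 5L))
  # fraction 1 -> every window is the whole chromosome
  ws_all <- build_windows(sm, 1)
  expect_true(all(ws_all$windows$first == 1 & ws_all$windows$last == 100))
  expect_error(build_windows(data.frame(id = "a", chrom = "1", pos = 1), 0.05),
               "fewer than 2")
})

test_that("nearest-neighbor members match a brute-force distance sort", {
  pos <- c(1, 2, 3, 10, 11, 12, 30)
  sm <- data.frame(id = paste0("s", 1:7), chrom = "1", pos = pos)
  ws <- build_windows(sm, 3 / 7)   # k = 3
  expect_true(all(ws$windows$k == 3))
  # spec example: anchor at position 10 takes {10, 11, 12}
  w4 <- ws$windows[4, ]
  expect_equal(ws$snp_map$pos[w4$first:w4$last], c(10, 11, 12))
  # oracle over all anchors: sort by (distance, index), take k, compare sets
  for (i in 1:7) {
    o <- order(abs(pos - pos[i]), seq_along(pos))[1:3]
    wi <- ws$windows[i, ]
    expect_setequal(wi$first:wi$last, sort(o))
  }
})

test_that("homozygosity indicator and locus weights follow their definitions", {
  expect_equal(unname(homozygosity_indicator(rbind(c(0L, 1L, 2L, NA)))),
               rbind(c(1, 0, 1, NA)))
  gm <- make_gm(rbind(c(0, 2, 2, 0), c(1, 1, 1, 1)))
  ind <- homozygosity_indicator(gm)
  expect_equal(unname(ind[1, ]), rep(1, 4))
  expect_equal(unname(ind[2, ]), rep(0, 4))
  expect_equal(locus_weights(c(0.30, 0.025, 0, 0.05)), c(1, 0.5, 0, 1))
  expect_error(locus_weights(c(0.2, 0.7)), "MAF outside")
})

test_that("intensity estimates are exact at the homozygous/heterozygous bounds", {
  set.seed(21)
  gm <- make_gm(matrix(2L, 3, 40), pos = sort(sample.int(1e6, 40)))
  ws <- build_windows(gm$snp_map, 0.2)
  v <- rep(1, 40)
  for (deg in 0:2) {
    prof <- estimate_intensity(homozygosity_indicator(gm), ws, v, degree = deg)
    expect_equal(unname(prof$H), matrix(1, 3, 40))
  }
  gm0 <- make_gm(matrix(1L, 3, 40), pos = gm$snp_map$pos)
  prof0 <- estimate_intensity(homozygosity_indicator(gm0), ws, v, degree = 1)
  expect_equal(unname(prof0$H), matrix(0, 3, 40))
})

test_that("degree-1 fit matches the explicit weighted-least-squares oracle", {
  # spec toy: u = (-1,-.5,0,.5,1), x = (1,1,0,1,1), v = 1, tricube kernel
  u <- c(-1, -0.5, 0, 0.5, 1)
  x <- c(1, 1, 0, 1, 1)
  pos <- 100 + u * 50
  gm_codes <- rbind(ifelse(x == 1, 2L, 1L))
  sm <- data.frame(id = paste0("s", 1:5), chrom = "1", pos = pos)
  ws <- build_windows(sm, 1)        # every window = all 5 SNPs
  prof <- estimate_intensity(rbind(x), ws, rep(1, 5), degree = 1)
  kw <- (1 - abs(u)^3)^3
  keep <- kw > 0
  expected <- oracle_wls_at0(u[keep], x[keep], kw[keep], degree = 1)
  expect_equal(unname(prof$H[1, 3]), clamp(expected, 0, 1), tolerance = 1e-10)

  # 100 random small windows, random locus weights (acceptance-grade check)
  set.seed(77)
  for (r in 1:100) {
    k <- sample(4:12, 1)
    pos <- sort(sample.int(1e5, k))
    anchor <- sample(k, 1)
    x <- rbinom(k, 1, 0.7)
    v <- runif(k, 0.2, 1)
    sm <- data.frame(id = paste0("s", 1:k), chrom = "1", pos = pos)
    ws <- build_windows(sm, 1)
    prof <- estimate_intensity(rbind(x), ws, v, degree = 1)
    u <- (pos - pos[anchor]) / max(abs(pos - pos[anchor]))
    w <- (1 - abs(u)^3)^3 * v
    keep <- w > 0
    expected <- if (qr(cbind(1, u[keep]) * sqrt(w[keep]))$rank == 2)
      oracle_wls_at0(u[keep], x[keep], w[keep], 1)
    else weighted.mean(x[keep], w[keep])
    expect_equal(unname(prof$H[1, anchor]), clamp(expected, 0, 1), tolerance = 1e-10)
  }
})

test_that("degree 0 equals the double-weighted mean and is monotone", {
  set.seed(31)
  k <- 9
  pos <- sort(sample.int(1e5, k))
  x <- rbinom(k, 1, 0.5)
  v <- runif(k, 0.1, 1)
  sm <- data.frame(id = paste0("s", 1:k), chrom = "1", pos = pos)
  ws <- build_windows(sm, 1)
  prof <- estimate_intensity(rbind(x), ws, v, degree = 0)
  for (a in 1:k) {
    u <- (pos - pos[a]) / max(abs(pos - pos[a]))
    w <- (1 - abs(u)^3)^3 * v
    expect_equal(unname(prof$H[1, a]), weighted.mean(x, w), tolerance = 1e-12)
  }
  # monotone response: flipping a 0 to 1 never decreases any window value
  i0 <- which(x == 0)[1]
  x2 <- x; x2[i0] <- 1
  prof2 <- estimate_intensity(rbind(x2), ws, v, degree = 0)
  expect_true(all(prof2$H >= prof$H - 1e-12))
})

test_that("missing genotypes are excluded, never imputed", {
  x <- rbind(c(1, NA, 1, 1, 0))
  sm <- data.frame(id = paste0("s", 1:5), chrom = "1", pos = c(1, 2, 3, 4, 5) * 100)
  ws <- build_windows(sm, 1)
  prof <- estimate_intensity(x, ws, rep(1, 5), degree = 0)
  pos <- sm$pos
  for (a in 1:5) {
    u <- (pos - pos[a]) / max(abs(pos - pos[a]))
    w <- (1 - abs(u)^3)^3
    ok <- !is.na(x[1, ])
    expect_equal(unname(prof$H[1, a]), weighted.mean(x[1, ok], w[ok]), tolerance = 1e-12)
  }
  # fully missing row -> all windows missing
  prof_na <- estimate_intensity(rbind(rep(NA_real_, 5)), ws, rep(1, 5))
  expect_true(all(is.na(prof_na$H)))
  # all locus weights zero -> missing
  prof_w0 <- estimate_intensity(rbind(c(1, 1, 1, 1, 1)), ws, rep(0, 5))
  expect_true(all(is.na(prof_w0$H)))
})

test_that("profile entries stay within [0,1] on random data", {
  set.seed(41)
  gm <- make_gm(matrix(sample(c(0:2, NA), 20 * 120, replace = TRUE,
                              prob = c(.3, .3, .3, .1)), 20, 120),
                pos = sort(sample.int(5e6, 120)))
  ws <- build_windows(gm$snp_map, 0.08)
  v <- locus_weights(snp_maf(gm))
  for (deg in 0:2) {
    prof <- estimate_intensity(homozygosity_indicator(gm), ws, v, degree = deg)
    h <- prof$H[!is.na(prof$H)]
    expect_true(all(h >= 0 & h <= 1))
  }
})

test_that("HD region extraction merges runs and applies both thresholds", {
  anchors <- seq(1e6, 13e6, by = 1e6)     # 13 anchors, 1 Mb apart
  h <- rep(0.95, 13)
  prof <- make_profile(h, anchors)
  reg <- extract_hd_regions(prof, 0.9, 5e6)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1e6); expect_equal(reg$end, 13e6)
  expect_equal(reg$length, 12e6 + 1)

  # 3 Mb run fails the 5 Mb threshold
  h2 <- c(rep(0.95, 4), rep(0.5, 9))
  expect_equal(nrow(extract_hd_regions(make_profile(h2, anchors), 0.9, 5e6)), 0)

  # two qualifying runs split by one cold window -> two regions; cross-check
  # with the exhaustive run-scan oracle
  h3 <- c(rep(0.95, 6), 0.5, rep(0.93, 6))
  reg3 <- extract_hd_regions(make_profile(h3, anchors), 0.9, 5e6)
  runs <- Filter(function(r) anchors[r[2]] - anchors[r[1]] + 1 >= 5e6,
                 oracle_runs(h3, 0.9))
  expect_equal(nrow(reg3), length(runs))
  for (i in seq_along(runs)) {
    expect_equal(reg3$start[i], anchors[runs[[i]][1]])
    expect_equal(reg3$end[i], anchors[runs[[i]][2]])
  }
  expect_true(all(reg3$mean_intensity >= 0.9))
})

test_that("HD summaries match the sort-based quantile oracle", {
  reg <- data.frame(sample = "I1", chrom = "1", start = 1,
                    end = c(5, 6, 7, 8, 9) * 1e6, length = c(5, 6, 7, 8, 9) * 1e6,
                    n_windows = 1L, mean_intensity = 0.95)
  s <- summarize_hd(reg)
  rl <- s[s$what == "region_length", ]
  expect_equal(unlist(rl[c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), c(5, 6, 7, 8, 9) * 1e6)
  # one sample with 5 Mb + 7 Mb -> total 12 Mb
  reg2 <- reg[reg$length %in% c(5e6, 7e6), ]
  s2 <- summarize_hd(reg2)
  expect_equal(s2[s2$what == "per_genome_total", "max"], 12e6)
  # 1000 simulated lengths vs the explicit type-7 formula
  set.seed(51)
  lens <- runif(1000, 5e6, 4e7)
  reg3 <- data.frame(sample = paste0("I", 1:1000), chrom = "1", start = 1,
                     end = lens, length = lens, n_windows = 1L,
                     mean_intensity = 1)
  s3 <- summarize_hd(reg3)
  rl3 <- s3[s3$what == "region_length", ]
  expect_equal(rl3$q1, oracle_q7(lens, 0.25), tolerance = 1e-12)
  expect_equal(rl3$median, oracle_q7(lens, 0.5), tolerance = 1e-12)
  expect_equal(rl3$q3, oracle_q7(lens, 0.75), tolerance = 1e-12)
  expect_equal(nrow(summarize_hd(reg[0, ])), 0)
})

test_that("a planted 10 Mb segment is recovered by profile + extraction", {
  cfg <- sim_config(n_families = 15, n_chromosomes = 1L,
                    snps_per_chromosome = 800, seed = 13)
  g <- simulate_genotypes(cfg)
  ind <- homozygosity_indicator(g$genotypes)
  ws <- build_windows(g$genotypes$snp_map, 0.05)
  prof <- estimate_intensity(ind, ws, locus_weights(snp_maf(g$genotypes)))
  seg <- g$truth$segments[1, ]
  srow <- match(seg$sample, rownames(prof$H))
  in_seg <- ws$windows$anchor_pos >= seg$start & ws$windows$anchor_pos <= seg$end
  expect_gte(mean(prof$H[srow, in_seg]), 0.9)
  reg <- extract_hd_regions(prof)
  reg_s <- reg[reg$sample == seg$sample, ]
  expect_gt(nrow(reg_s), 0)
  overlap <- max(pmin(reg_s$end, seg$end) - pmax(reg_s$start, seg$start) + 1)
  expect_gte(overlap / (seg$end - seg$start + 1), 0.8)
})
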