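test_that("a planted consensus site is recovered at its offset", {
  bg <- uniform_bg()
  pwm <- generate_pwm(10, 16, bg, seed = 71, name = "hi")
  calib <- calibrate_all(list(pwm), bg)
  e <- generate_enhancer(150, list(hi = pwm), 1, bg, seed = 72, id = "e1")
  h <- find_hits(e$record$sequence, calib, enhancer_id = "e1")
  expect_true(nrow(h) >= 1)
  expect_true(e$truth$offset %in% h$offset)
  expect_equal(h$strand[h$offset == e$truth$offset], e$truth$strand)
})

test_that("an enhancer shorter than every motif yields an empty table, not an error", {
  bg <- uniform_bg()
  pwm <- generate_pwm(12, 14, bg, seed = 73)
  calib <- calibrate_all(list(pwm), bg)
  h <- find_hits("ACGTACGT", calib, enhancer_id = "short")
  expect_equal(nrow(h), 0L)
  expect_named(h, c("enhancer_id", "tf_name", "offset", "strand",
                    "score", "ln_pvalue"))
})

test_that("hit tables are deterministic and respect the calibrated cutoff", {
  bg <- at_rich_bg()
  pwms <- list(generate_pwm(8, 8, bg, seed = 74, name = "a"),
               generate_pwm(10, 10, bg, seed = 75, name = "b"))
  calib <- calibrate_all(pwms, bg)
  seq <- generate_background(5000, bg, seed = 76)
  h1 <- find_hits(seq, calib, enhancer_id = "x")
  h2 <- find_hits(seq, calib, enhancer_id = "x")
  expect_identical(h1, h2)
  # every hit is at or below its motif's cutoff and inside the sequence
  for (tf in unique(h1$tf_name)) {
    expect_true(all(h1$ln_pvalue[h1$tf_name == tf] <= calib$cutoffs[[tf]]))
  }
  widths <- sapply(calib$pwms, function(p) p$width)
  expect_true(all(h1$offset >= 0 & h1$offset + widths[h1$tf_name] <= 5000))
  # ordering contract: (offset, tf_name, strand)
  expect_false(is.unsorted(order(h1$offset, h1$tf_name, h1$strand)))
})

test_that("background hit frequency matches the score-distribution tail probability", {
  bg <- at_rich_bg()
  pwm <- generate_pwm(9, 11, bg, seed = 77)
  calib <- calibrate_all(list(pwm), bg)
  seq <- generate_background(40000, bg, seed = 78)
  h <- find_hits(seq, calib)
  sd <- calib$sdists[[1]]
  pass_bins <- sd$bins[sd$ln_tail <= calib$cutoffs[[1]]]
  p <- exp(sd$ln_tail[match(min(pass_bins), sd$bins)])
  n <- (40000 - 9 + 1) * 2
  expect_lt(abs(nrow(h) - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
})

test_that("most planted sites of a specific motif are recovered", {
  bg <- at_rich_bg()
  pwm <- generate_pwm(10, 12, bg, seed = 79, name = "tf12")
  calib <- calibrate_all(list(pwm), bg, percentile = 75)
  recovered <- 0L; planted <- 0L
  for (s in 1:10) {
    e <- generate_enhancer(400, list(tf12 = pwm), 4, bg, seed = 80 + s)
    h <- find_hits(e$record$sequence, calib, enhancer_id = e$record$id)
    planted <- planted + nrow(e$truth)
    recovered <- recovered +
      sum(mapply(function(o, st) any(h$offset == o & h$strand == st),
                 e$truth$offset, e$truth$strand))
  }
  expect_gte(recovered / planted, 0.70)
})

test_that("non-overlapping pruning keeps a most-significant consistent subset", {
  bg <- uniform_bg()
  # low-content motif on permissive calibration gives dense overlapping hits
  pwm <- generate_pwm(6, 4, bg, seed = 91, name = "lo")
  calib <- calibrate_all(list(pwm), bg, percentile = 90)
  seq <- generate_background(2000, bg, seed = 92)
  all_h <- find_hits(seq, calib)
  pruned <- find_hits(seq, calib, non_overlapping = TRUE)
  expect_lte(nrow(pruned), nrow(all_h))
  if (nrow(pruned) > 1) {
    o <- sort(pruned$offset)
    expect_true(all(diff(o) >= 6))
  }
})

test_that("profiles aggregate hits into the compared metrics", {
  bg <- uniform_bg()
  pwms <- lapply(1:10, function(i) {
    generate_pwm(8, 10, bg, seed = 100 + i, name = paste0("tf", i))
  })
  calib <- calibrate_all(pwms, bg)
  # zero hits: p_av undefined, normalised count zero
  p0 <- profile_enhancer("e0", "g", 500, find_hits(paste(rep("A", 0), collapse = ""),
                                                   calib, enhancer_id = "e0"), calib)
  expect_equal(p0$n_total, 0L)
  expect_equal(p0$normalized_sites, 0)
  expect_true(is.na(p0$p_av))

  # synthetic hit table {tf1: 3, tf2: 1} over a 10-motif panel
  hits <- data.frame(enhancer_id = "e1", tf_name = c("tf1", "tf1", "tf1", "tf2"),
                     offset = c(0L, 10L, 20L, 30L), strand = "+",
                     score = 1, ln_pvalue = -5)
  pr <- profile_enhancer("e1", "g", 500, hits, calib)
  expect_equal(pr$n_total, 4L)
  expect_equal(pr$n_motifs_searched, 10L)
  expect_equal(pr$normalized_sites, 0.4)
  I1 <- calib$info[["tf1"]]; I2 <- calib$info[["tf2"]]
  expect_equal(pr$p_av, (3 * 2^-I1 + 1 * 2^-I2) / 4)
  expect_equal(sum(attr(pr, "per_tf_counts")), pr$n_total)
  expect_error(profile_enhancer("other", "g", 500, hits, calib), "different enhancer")
})

test_that("cohort profiling uses each group's own panel and flags orphans", {
  bg <- at_rich_bg()
  panelA <- lapply(1:4, function(i) generate_pwm(8, 9, bg, seed = 110 + i,
                                                 name = paste0("A", i)))
  panelB <- lapply(1:2, function(i) generate_pwm(8, 9, bg, seed = 120 + i,
                                                 name = paste0("B", i)))
  calibs <- list(gA = calibrate_all(panelA, bg), gB = calibrate_all(panelB, bg))
  enh <- do.call(rbind, lapply(1:6, function(i) {
    g <- if (i <= 3) "gA" else if (i <= 5) "gB" else "gC"
    data.frame(id = paste0("e", i), group = g,
               sequence = generate_background(300, bg, seed = 130 + i),
               length_bp = 300L)
  }))
  out <- profile_cohort(enh, calibs)
  expect_equal(nrow(out$profiles), 5L)
  # normalised counts divide by each group's own motif-panel size
  expect_true(all(out$profiles$n_motifs_searched[out$profiles$group == "gA"] == 4L))
  expect_true(all(out$profiles$n_motifs_searched[out$profiles$group == "gB"] == 2L))
  expect_equal(out$unprofiled$id, "e6")
  expect_match(out$unprofiled$reason, "no motif panel")
})

test_that("interval overlap fractions follow the half-open 1-bp rule", {
  a <- data.frame(chrom = "chr2L", start = c(0, 500), end = c(100, 600))
  expect_equal(overlap_fraction(a, a)$fraction, 1.0)
  b_disjoint <- data.frame(chrom = "chr2L", start = c(200, 700), end = c(300, 800))
  expect_equal(overlap_fraction(a, b_disjoint)$fraction, 0.0)
  # 1 bp of overlap counts as partial
  b_edge <- data.frame(chrom = "chr2L", start = 99, end = 200)
  ov <- overlap_fraction(a, b_edge)
  expect_equal(ov$fraction, 0.5)
  expect_equal(ov$per_interval$best_overlap_fraction, c(1 / 100, 0))
  # different chromosome never overlaps
  b_chr <- data.frame(chrom = "chr3R", start = 0, end = 1000)
  expect_equal(overlap_fraction(a, b_chr)$fraction, 0.0)
  expect_error(overlap_fraction(a[0, ], a), "empty")
  expect_error(overlap_fraction(data.frame(start = 5, end = 5), a), "start < end")
})
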