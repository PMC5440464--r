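test_that("pseudocounting follows the intergenic-proportional formula", {
  bg <- uniform_bg()
  pwm <- build_pwm(toy_counts()[, 1, drop = FALSE], bg)
  # column (A=10, C=0, G=0, T=0), uniform q: p(A) = 10.0025/10.01
  expect_equal(unname(pwm$freqs["A", 1]), (10 + 0.01 * 0.25) / 10.01)
  expect_equal(unname(pwm$freqs["C", 1]), (0.01 * 0.25) / 10.01)

  # frequency-normalised column (mass 1), skewed background
  bg2 <- background_model(q = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  pwm2 <- build_pwm(matrix(c(1, 0, 0, 0), 4), bg2)
  expect_equal(unname(pwm2$freqs["A", 1]), (1 + 0.01 * 0.3) / 1.01)
  # columns always renormalise to exactly 1
  expect_true(all(abs(colSums(pwm2$freqs) - 1) < 1e-9))
  expect_true(all(pwm2$freqs > 0))
})

test_that("a PWM rebuilt from a sampled alignment recovers the generator frequencies", {
  bg <- uniform_bg()
  src <- generate_pwm(8, 9, bg, seed = 41, n_train = 400)
  truef <- attr(src, "sampling_freqs")
  rebuilt <- build_pwm(src$training, bg)
  n <- 400
  # every cell within 3 sigma of its binomial sampling error (plus pseudocount slack)
  sigma <- sqrt(truef * (1 - truef) / n)
  expect_true(all(abs(rebuilt$freqs - truef) <= 3 * sigma + 0.01))
})

test_that("build_pwm rejects degenerate input", {
  bg <- uniform_bg()
  expect_error(build_pwm(character(0), bg), "empty")
  expect_error(build_pwm(c("ACGT", "ACNT"), bg), "ambiguity")
  expect_error(build_pwm(c("ACGT", "ACG"), bg), "equal length")
  expect_error(build_pwm(matrix(-1, 4, 2), bg), "non-negative")
  expect_error(build_pwm(matrix(0, 4, 2), bg), "positive total")
})

test_that("log-odds weights are zero for a background-identical motif", {
  bg <- at_rich_bg()
  f <- matrix(rep(bg$q, 3), nrow = 4)
  # counts proportional to q with zero pseudocount keep p = q exactly
  pwm <- build_pwm(f, bg, pseudocount_total = 0)
  W <- log_odds_matrix(pwm, bg)
  expect_equal(max(abs(W)), 0, tolerance = 1e-12)
  expect_equal(information_content(pwm, bg), 0, tolerance = 1e-12)
})

test_that("log-odds single-cell arithmetic and argmax-string maximality", {
  bg <- uniform_bg()
  pwm <- build_pwm(matrix(c(0.97, 0.01, 0.01, 0.01), 4), bg,
                   pseudocount_total = 0)
  W <- log_odds_matrix(pwm, bg)
  expect_equal(unname(W["A", 1]), log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(unname(W["A", 1]), 1.956, tolerance = 1e-3)

  # for L = 4, the per-column argmax string maximises the score over all 4^L
  pwm4 <- build_pwm(toy_counts()[, 1:4], bg)
  W4 <- log_odds_matrix(pwm4, bg)
  enum <- enumerate_score_distribution(W4, bg$q)
  best <- max(enum$score)
  argmax <- paste(c("A", "C", "G", "T")[apply(W4, 2, which.max)], collapse = "")
  expect_equal(naive_window_score(W4, argmax), best, tolerance = 1e-9)
})

test_that("score_sequence matches a naive per-window sum on both strands", {
  bg <- at_rich_bg()
  pwm <- generate_pwm(5, 7, bg, seed = 5)
  W <- log_odds_matrix(pwm, bg)
  set.seed(99)
  seq50 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  sc <- score_sequence(W, seq50, strands = "both")
  expect_equal(nrow(sc), 46 * 2)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in sample(nrow(sc), 12)) {
    win <- substr(seq50, sc$offset[i] + 1, sc$offset[i] + 5)
    if (sc$strand[i] == "-") win <- revcomp(win)
    expect_equal(sc$score[i], naive_window_score(W, win), tolerance = 1e-9)
  }
})

test_that("scoring reports the best hit for the consensus and skips ambiguous windows", {
  bg <- uniform_bg()
  pwm <- build_pwm(toy_counts()[, 1:4], bg)
  W <- log_odds_matrix(pwm, bg)
  sc <- score_sequence(W, "ACGT", strands = "forward")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$offset, 0L)
  expect_equal(sc$score, sum(apply(W, 2, max)), tolerance = 1e-9)

  # non-ACGT characters knock out the windows that cover them
  scN <- score_sequence(W, "ACGTNACGT", strands = "forward")
  expect_equal(scN$offset, c(0L, 5L))
  expect_error(score_sequence(W, "ACG"), "too short")
})

test_that("palindromic weights give equal forward and reverse scores", {
  bg <- uniform_bg()
  W <- log_odds_matrix(build_pwm(toy_counts()[, 1:4], bg), bg)
  # columns: X, Y, revcomp(Y), revcomp(X) -> palindromic weight matrix
  Wp <- cbind(W[, 1], W[, 2], W[4:1, 2], W[4:1, 1])
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  sc <- score_sequence(Wp, s, strands = "both")
  fwd <- sc[sc$strand == "+", ]
  rev <- sc[sc$strand == "-", ]
  expect_equal(fwd$score, rev$score, tolerance = 1e-9)
})

test_that("score distribution matches exhaustive enumeration", {
  bg <- at_rich_bg()
  # L = 1 near-deterministic column, uniform background
  bgu <- uniform_bg()
  pwm1 <- build_pwm(matrix(c(1, 0, 0, 0), 4), bgu)
  W1 <- log_odds_matrix(pwm1, bgu)
  sd1 <- score_distribution(W1, bgu)
  expect_equal(ln_pvalue(sd1, max(W1)), log(0.25), tolerance = 1e-9)
  expect_equal(ln_pvalue(sd1, min(W1)), 0)

  # L = 2 and L = 4 arbitrary matrices vs full 4^L enumeration, within one bin
  for (prm in list(list(L = 2, seed = 13, I = 2.5), list(L = 4, seed = 17, I = 5))) {
    pwm <- generate_pwm(prm$L, prm$I, bg, seed = prm$seed)
    W <- log_odds_matrix(pwm, bg)
    sd <- score_distribution(W, bg, bin_width = 0.01)
    # enumeration on the same discretised weights the DP uses: exact agreement
    Wd <- sd$iweights * sd$bin_width
    enum <- enumerate_score_distribution(Wd, bg$q)
    for (i in seq_along(enum$score)) {
      tail_true <- sum(enum$prob[enum$score >= enum$score[i] - 1e-9])
      expect_equal(ln_pvalue(sd, enum$score[i]), log(tail_true), tolerance = 1e-9)
    }
    # enumeration on the exact weights: agreement within one bin per position
    enum_exact <- enumerate_score_distribution(W, bg$q)
    slack <- prm$L * sd$bin_width
    for (s in enum_exact$score) {
      lo <- log(sum(enum_exact$prob[enum_exact$score >= s - slack]))
      hi <- log(sum(c(0, enum_exact$prob[enum_exact$score >= s + slack])))
      lp <- ln_pvalue(sd, s)
      expect_true(lp <= lo + 1e-9 && lp >= hi - 1e-9)
    }
  }
})

test_that("ln(p-value) is a proper tail function", {
  bg <- at_rich_bg()
  pwm <- generate_pwm(6, 8, bg, seed = 23)
  sd <- score_distribution(log_odds_matrix(pwm, bg), bg)
  expect_true(all(diff(sd$ln_tail) <= 1e-12))      # non-increasing in score
  expect_equal(sd$ln_tail[1], 0)                    # P(score >= min) = 1
  expect_equal(sum(sd$prob), 1, tolerance = 1e-9)   # total mass
  # tail at the maximum score equals the probability of the argmax string
  pmax_str <- prod(bg$q[apply(sd$iweights, 2, which.max)])
  expect_equal(sd$ln_tail[length(sd$ln_tail)], log(pmax_str), tolerance = 1e-9)
  expect_error(score_distribution(log_odds_matrix(pwm, bg), bg, bin_width = 0),
               "positive")
})

test_that("information content and hit probability are mutually consistent", {
  bg <- uniform_bg()
  # deterministic 5-position motif: 2 bits/position minus pseudocount correction
  pwm <- build_pwm(matrix(rep(c(1, 0, 0, 0), 5), nrow = 4), bg)
  # direct formula evaluation at the pseudocounted frequencies (oracle)
  pA <- (1 + 0.01 * 0.25) / 1.01; pO <- (0.01 * 0.25) / 1.01
  I_col <- pA * log2(pA / 0.25) + 3 * pO * log2(pO / 0.25)
  expect_equal(information_content(pwm, bg), 5 * I_col, tolerance = 1e-12)
  expect_lt(information_content(pwm, bg), 10)   # below the no-pseudocount bound
  expect_gt(information_content(pwm, bg), 9.5)

  expect_equal(motif_hit_probability(0), 1)
  expect_equal(motif_hit_probability(10), 2^-10)
  # the hit probabilities quoted for the specificity quartiles
  expect_equal(motif_hit_probability(-log2(2e-3)), 2e-3)
  expect_equal(motif_hit_probability(14.02), 6e-5, tolerance = 0.01)
  expect_error(motif_hit_probability(-1), ">= 0")
})

test_that("average motif hit probability is a count-weighted mean", {
  expect_equal(average_motif_hit_probability(5, 9), 2^-9)
  expect_equal(average_motif_hit_probability(c(1, 1), c(8, 10)),
               (2^-8 + 2^-10) / 2)
  # hand summation oracle
  expect_equal(average_motif_hit_probability(c(3, 1), c(8.97, 14.02)),
               (3 * 2^-8.97 + 1 * 2^-14.02) / 4)
  # invariant to uniform count scaling; bounded by the extreme per-TF values
  pav <- average_motif_hit_probability(c(3, 1), c(8.97, 14.02))
  expect_equal(average_motif_hit_probability(c(30, 10), c(8.97, 14.02)), pav)
  expect_true(pav >= 2^-14.02 && pav <= 2^-8.97)
  expect_error(average_motif_hit_probability(c(0, 0), c(8, 10)), "undefined")
})

test_that("motif files round-trip through both dialects", {
  bg <- at_rich_bg()
  dir <- withr::local_tempdir()
  pwm <- generate_pwm(6, 8, bg, seed = 31, name = "tfA")
  path <- file.path(dir, "tfA.pwm")
  write_pwm_file(pwm, path)
  back <- read_pwm_file(path, bg)
  expect_equal(back$name, "tfA")
  expect_equal(back$freqs, pwm$freqs, tolerance = 1e-4)
  expect_equal(length(back$training), length(pwm$training))

  # JASPAR-style dialect
  jas <- c(">MA0001.1 tfB",
           "A [ 4 19  0  0 ]",
           "C [16  0 20  0 ]",
           "G [ 0  1  0 20 ]",
           "T [ 0  0  0  0 ]")
  jpath <- file.path(dir, "tfB.jaspar")
  writeLines(jas, jpath)
  jpwm <- read_pwm_file(jpath, bg)
  expect_equal(jpwm$name, "tfB")
  expect_equal(jpwm$width, 4L)
  expect_equal(unname(jpwm$counts["C", 1]), 16)
})

test_that("background composition can be estimated from FASTA", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "intergenic.fasta")
  writeLines(c(">r1", "AAAATTTT", ">r2", "CCGG"), fa)
  bg <- background_from_fasta(fa)
  expect_equal(unname(bg$q), c(4, 2, 2, 4) / 12)
  expect_error(background_model(q = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(background_model(q = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})
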