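#' Log-odds scoring matrix
#'
#' Per-position weights `log2(p_i(b) / q(b))` in bits. A window's score is
#' the sum of the weights of its bases.
#'
#' @param pwm A [build_pwm] object (pseudocounted; no zero frequencies).
#' @param background A [background_model].
#' @return A 4 x L numeric matrix (rows A, C, G, T) of weights in bits.
#' @export
log_odds_matrix <- function(pwm, background) {
  stopifnot(inherits(pwm, "pwm"), inherits(background, "background_model"))
  if (any(pwm$freqs <= 0)) stop("PWM has zero frequencies; pseudocount first")
  log2(sweep(pwm$freqs, 1L, background$q, "/"))
}

# weight matrix for reverse-strand scoring at forward offsets:
# scoring window w with this matrix == scoring revcomp(w) with W
revcomp_weights <- function(W) {
  W[4:1, rev(seq_len(ncol(W))), drop = FALSE]
}

# vectorised window scores for an integer-encoded sequence;
# windows containing non-ACGT characters come back NA
window_scores_int <- function(ints, W) {
  L <- ncol(W)
  nw <- length(ints) - L + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + W[cbind(ints[j:(nw + j - 1L)], j)]
  }
  sc
}

#' Score every window of a sequence
#'
#' Slides the motif along the sequence and reports the log-odds score of each
#' window on the requested strands. Reverse-strand windows are scored on the
#' reverse complement and reported at the forward-strand offset. Windows
#' containing non-ACGT characters are skipped.
#'
#' @param weights 4 x L log-odds matrix from [log_odds_matrix].
#' @param seq DNA string, length >= L.
#' @param strands `"both"` or `"forward"`.
#' @return Data frame with columns `offset` (0-based), `strand`, `score`
#'   (bits), ordered by offset then strand.
#' @export
score_sequence <- function(weights, seq, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  L <- ncol(weights)
  ints <- encode_dna(seq)
  if (length(ints) < L) {
    stop("sequence too short: ", length(ints), " < motif width ", L)
  }
  fwd <- window_scores_int(ints, weights)
  out <- data.frame(offset = seq_along(fwd) - 1L, strand = "+", score = fwd)
  if (strands == "both") {
    rev <- window_scores_int(ints, revcomp_weights(weights))
    out <- rbind(out,
                 data.frame(offset = seq_along(rev) - 1L, strand = "-", score = rev))
  }
  out <- out[!is.na(out$score), , drop = FALSE]
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact score distribution under the background model
#'
#' Discretises the log-odds weights to a fixed bin width and computes, by
#' position-wise convolution (Staden / Hertz–Stormo dynamic programming), the
#' exact probability distribution of the window score at a random background
#' position, and from it the natural-log tail probability
#' `ln P(score >= s)` for every achievable score.
#'
#' @param weights 4 x L log-odds matrix (bits).
#' @param background A [background_model].
#' @param bin_width Score discretisation step in bits (default 0.01).
#' @return An object of class `score_distribution`: `bin_width`, `iweights`
#'   (integer bin matrix used for all downstream scoring), `bins` (integer
#'   bin indices of achievable scores), `prob` (their probabilities),
#'   `ln_tail` (ln upper-tail probability at each bin), `q`.
#' @export
score_distribution <- function(weights, background, bin_width = 0.01) {
  stopifnot(inherits(background, "background_model"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  if (any(!is.finite(weights))) stop("weights must be finite")
  iW <- round(weights / bin_width)
  storage.mode(iW) <- "integer"
  q <- background$q
  L <- ncol(iW)

  lo <- 0L; hi <- 0L
  prob <- 1
  for (j in seq_len(L)) {
    col <- iW[, j]
    new_lo <- lo + min(col)
    new_hi <- hi + max(col)
    nv <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- (lo + col[b]) - new_lo  # 0-based start of shifted block
      idx <- (sh + 1L):(sh + length(prob))
      nv[idx] <- nv[idx] + prob * q[b]
    }
    prob <- nv; lo <- new_lo; hi <- new_hi
  }
  tail <- rev(cumsum(rev(prob)))
  tail <- pmin(tail, 1)
  structure(list(bin_width = bin_width, iweights = iW,
                 bins = lo:hi, prob = prob, ln_tail = log(tail), q = q),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "Score distribution: width %d, bin %.3g bits, scores in [%.2f, %.2f], min ln(p) = %.2f\n",
    ncol(x$iweights), x$bin_width,
    min(x$bins) * x$bin_width, max(x$bins) * x$bin_width,
    x$ln_tail[length(x$ln_tail)]))
  invisible(x)
}

# ln P(score >= iscore) for integer bin scores (vectorised)
ln_tail_at_bin <- function(sdist, iscore) {
  lo <- sdist$bins[1L]; hi <- sdist$bins[length(sdist$bins)]
  idx <- pmax(iscore, lo) - lo + 1L
  out <- ifelse(iscore > hi, -Inf, sdist$ln_tail[idx])
  as.numeric(out)
}

#' ln(p-value) of a score threshold
#'
#' Natural-log probability that a random background window scores at or
#' above `score`. Non-increasing in `score`; equals 0 at or below the
#' minimum achievable score.
#'
#' @param sdist A [score_distribution].
#' @param score Score threshold(s) in bits.
#' @return ln(p-value), same length as `score` (`-Inf` above the maximum
#'   achievable score).
#' @export
ln_pvalue <- function(sdist, score) {
  stopifnot(inherits(sdist, "score_distribution"))
  ln_tail_at_bin(sdist, as.integer(round(score / sdist$bin_width)))
}

# best (max) integer window score over requested strands; NA windows dropped.
# Returns list(fwd=, rev=) of integer vectors aligned to forward offsets.
window_iscores <- function(ints, sdist, strands = "both") {
  iW <- sdist$iweights
  fwd <- window_scores_int(ints, iW)
  rev <- if (strands == "both") window_scores_int(ints, revcomp_weights(iW)) else NULL
  list(fwd = fwd, rev = rev)
}
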