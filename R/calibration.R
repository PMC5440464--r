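best_training_ln_pvalue <- function(seq, sdist, strands = "both") {
  ints <- encode_dna(seq)
  if (length(ints) < ncol(sdist$iweights)) return(NA_real_)
  sc <- window_iscores(ints, sdist, strands)
  all <- c(sc$fwd, sc$rev)
  all <- all[!is.na(all)]
  if (length(all) == 0L) return(NA_real_)
  ln_tail_at_bin(sdist, max(all))
}

#' Calibrate a ln(p-value) cutoff on the motif's training alignment
#'
#' Scores the aligned sequences the PWM was built from and sets the
#' threshold so that a chosen percentage of them qualify as true binding
#' sites: each training sequence is assigned its best (smallest) ln(p-value)
#' over all offsets and strands, and the cutoff is the nearest-rank
#' `percentile`-th order statistic of those values in ascending order, so
#' that at least `percentile`% of training sequences pass their own cutoff.
#' Sequences shorter than the motif cannot be scored and are excluded
#' (counted as skipped).
#'
#' @param pwm A [build_pwm] object carrying a non-empty training alignment.
#' @param background A [background_model].
#' @param percentile Percentage of training sequences that must qualify
#'   (default 75).
#' @param strands `"both"` or `"forward"`.
#' @param bin_width Score discretisation (see [score_distribution]).
#' @return An object of class `cutoff_result`: `tf_name`, `percentile`,
#'   `cutoff_ln_pvalue`, `n_training_used`, `n_training_skipped`,
#'   `per_sequence_ln_pvalue`, and the `score_distribution` used (`sdist`).
#' @export
calibrate_cutoff <- function(pwm, background, percentile = 75,
                             strands = c("both", "forward"),
                             bin_width = 0.01) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"), percentile > 0, percentile <= 100)
  if (is.null(pwm$training) || length(pwm$training) == 0L) {
    stop("PWM '", pwm$name, "' has no training alignment to calibrate on")
  }
  W <- log_odds_matrix(pwm, background)
  sdist <- score_distribution(W, background, bin_width)
  lnp <- vapply(pwm$training, best_training_ln_pvalue, numeric(1),
                sdist = sdist, strands = strands, USE.NAMES = FALSE)
  skipped <- sum(is.na(lnp))
  lnp <- lnp[!is.na(lnp)]
  if (length(lnp) == 0L) {
    stop("all training sequences of '", pwm$name,
         "' are shorter than the motif (or unscorable)")
  }
  sorted <- sort(lnp)
  idx <- ceiling(percentile / 100 * length(sorted))
  structure(list(tf_name = pwm$name, percentile = percentile,
                 cutoff_ln_pvalue = sorted[idx],
                 n_training_used = length(lnp),
                 n_training_skipped = skipped,
                 per_sequence_ln_pvalue = lnp,
                 sdist = sdist, strands = strands),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("'%s': %gth-percentile cutoff ln(p) = %.3f (%d training used, %d skipped)\n",
              x$tf_name, x$percentile, x$cutoff_ln_pvalue,
              x$n_training_used, x$n_training_skipped))
  invisible(x)
}

#' Calibrate a set of motifs
#'
#' Runs [calibrate_cutoff] over a motif panel. Motifs whose training data
#' are unusable (missing alignment, or every sequence shorter than the
#' motif) are reported as skipped in the table, never silently dropped.
#'
#' @param pwms List of [build_pwm] objects (names taken from each PWM).
#' @param background A [background_model].
#' @param percentile Percentage of training sequences that must qualify.
#' @param strands `"both"` or `"forward"`.
#' @param bin_width Score discretisation step.
#' @return An object of class `motif_calibration`: `pwms` (the calibratable
#'   ones, named), `cutoffs` (named ln(p-value) thresholds), `sdists`,
#'   `info` (named information contents, bits), `table` (one row per input
#'   PWM including skipped ones with a `reason`), `percentile`, `strands`,
#'   `background`.
#' @export
calibrate_all <- function(pwms, background, percentile = 75,
                          strands = c("both", "forward"), bin_width = 0.01) {
  strands <- match.arg(strands)
  stopifnot(length(pwms) >= 1L)
  rows <- list(); keep <- list(); sdists <- list(); cutoffs <- c(); info <- c()
  for (pwm in pwms) {
    res <- tryCatch(
      calibrate_cutoff(pwm, background, percentile, strands, bin_width),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = pwm$name, percentile = percentile,
        cutoff_ln_pvalue = NA_real_, n_training_used = 0L,
        n_training_skipped = if (is.null(pwm$training)) 0L else length(pwm$training),
        information_content = NA_real_, skipped = TRUE, reason = res)
      next
    }
    I <- information_content(pwm, background)
    rows[[length(rows) + 1L]] <- data.frame(
      tf_name = res$tf_name, percentile = percentile,
      cutoff_ln_pvalue = res$cutoff_ln_pvalue,
      n_training_used = res$n_training_used,
      n_training_skipped = res$n_training_skipped,
      information_content = I, skipped = FALSE, reason = "")
    keep[[pwm$name]] <- pwm
    sdists[[pwm$name]] <- res$sdist
    cutoffs[pwm$name] <- res$cutoff_ln_pvalue
    info[pwm$name] <- I
  }
  if (length(keep) == 0L) stop("no PWM in the set could be calibrated")
  structure(list(pwms = keep, cutoffs = cutoffs, sdists = sdists,
                 info = info, table = do.call(rbind, rows),
                 percentile = percentile, strands = strands,
                 background = background),
            class = "motif_calibration")
}

#' @export
print.motif_calibration <- function(x, ...) {
  cat(sprintf("Motif calibration: %d motifs at percentile %g (%d skipped)\n",
              length(x$pwms), x$percentile, sum(x$table$skipped)))
  invisible(x)
}
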