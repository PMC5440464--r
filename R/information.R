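#' Motif information content (bits)
#'
#' Kullback-Leibler divergence between the motif's per-position base
#' frequencies and the background composition:
#' \deqn{I = \sum_{i=1}^{L} \sum_{b} p_i(b) \log_2 \frac{p_i(b)}{q(b)}}
#' Higher information content means higher binding specificity.
#'
#' @param pwm A [build_pwm] object.
#' @param background A [background_model].
#' @return Information content in bits (non-negative).
#' @export
information_content <- function(pwm, background) {
  stopifnot(inherits(pwm, "pwm"), inherits(background, "background_model"))
  f <- pwm$freqs
  sum(f * log2(sweep(f, 1L, background$q, "/")))
}

#' Motif hit probability from information content
#'
#' The probability that a random background position matches the motif,
#' approximated as `p = 2^-I` for a motif of information content `I` bits.
#'
#' @param I Information content in bits (non-negative, vectorised).
#' @return Hit probability in (0, 1].
#' @export
motif_hit_probability <- function(I) {
  if (any(!is.finite(I)) || any(I < 0)) stop("information content must be >= 0")
  2^(-I)
}

#' Average motif hit probability of an enhancer
#'
#' Site-count-weighted mean of per-TF hit probabilities:
#' \deqn{p_{av} = \frac{\sum_j n_j 2^{-I_j}}{\sum_j n_j}}
#' the enhancer-level average specificity of the TFs that actually hit it.
#'
#' @param site_counts Per-TF binding-site counts `n_j` (non-negative; at
#'   least one positive).
#' @param contents Per-TF information contents `I_j` in bits, index-aligned
#'   with `site_counts`.
#' @return `p_av`, between `min(2^-I_j)` and `max(2^-I_j)` over TFs with
#'   positive counts.
#' @export
average_motif_hit_probability <- function(site_counts, contents) {
  if (length(site_counts) != length(contents)) {
    stop("site_counts and contents must be index-aligned")
  }
  if (any(site_counts < 0)) stop("site counts must be non-negative")
  n_total <- sum(site_counts)
  if (n_total == 0) stop("all site counts are zero: p_av is undefined")
  sum(site_counts * motif_hit_probability(contents)) / n_total
}
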