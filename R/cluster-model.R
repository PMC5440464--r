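#' Accessible genome sizes (bp)
#'
#' Named constants for the size of the genome accessible to transcription
#' factor binding in the early Drosophila embryo: a conservative
#' DNase-hypersensitivity estimate (4.1 Mb), a relaxed estimate (19.4 Mb),
#' and the whole genome (175.5 Mb).
#'
#' @format Named numeric vector of length 3 (base pairs).
#' @export
accessible_genome_sizes <- c(
  dnase_conservative = 4.1e6,
  dnase_relaxed      = 19.4e6,
  whole_genome       = 175.5e6
)

#' Resolve an accessible genome size
#'
#' Accepts either a number of base pairs or one of the names of
#' [accessible_genome_sizes].
#'
#' @param N Numeric genome size in bp, or a name such as `"whole_genome"`.
#' @return Genome size in bp.
#' @export
resolve_genome_size <- function(N) {
  if (is.character(N)) {
    if (!N %in% names(accessible_genome_sizes)) {
      stop("unknown genome size name '", N, "'; known: ",
           paste(names(accessible_genome_sizes), collapse = ", "))
    }
    return(unname(accessible_genome_sizes[[N]]))
  }
  stopifnot(is.numeric(N), length(N) == 1L, N > 0)
  as.numeric(N)
}

check_cluster_domain <- function(w, k = 0L, p, m = 1L, N = NULL) {
  stopifnot(length(w) == 1L, length(p) == 1L, length(m) == 1L)
  if (w < 1 || w != round(w)) stop("enhancer length w must be a positive integer")
  if (w > 1e6) stop("w > 1e6 not supported (runtime guard)")
  if (m < 1 || m != round(m)) stop("number of TFs m must be a positive integer")
  if (!is.finite(p) || p <= 0) stop("motif hit probability p must be in (0, 1)")
  if (m * p >= 1) stop("m*p = ", m * p, " >= 1: parameters outside model domain")
  if (any(k < 0) || any(k != round(k))) stop("site count k must be a non-negative integer")
  if (any(k > w)) stop("site count k exceeds enhancer length w")
  if (!is.null(N) && N < w) stop("accessible genome size N must be >= w")
  invisible(TRUE)
}

#' Probability of a binding-site cluster
#'
#' Point binomial probability of observing exactly `k` binding sites in an
#' enhancer of length `w` bp, where each position is a motif hit with
#' probability `p`. When the cluster is composed of sites of `m` different
#' TFs with identical hit probability, the per-position hit probability is
#' `m*p`:
#' \deqn{P(k) = \binom{w}{k} (mp)^k (1 - mp)^{w-k}}
#'
#' Computed in log space, underflow-safe for `w` up to `1e5` and
#' probabilities down to `1e-300`.
#'
#' @param w Enhancer length (bp, positive integer).
#' @param k Number of binding sites (non-negative integer, vectorised).
#' @param p Motif hit probability per position, in (0, 1).
#' @param m Number of distinct TFs contributing sites (default 1).
#' @param log If `TRUE`, return the log probability.
#' @return Probability (or log probability), same length as `k`.
#' @examples
#' cluster_probability(1000, 13, 2e-3)
#' @export
cluster_probability <- function(w, k, p, m = 1L, log = FALSE) {
  check_cluster_domain(w, k, p, m)
  stats::dbinom(k, size = w, prob = m * p, log = log)
}

#' Minimum binding sites for distinguishability
#'
#' Smallest site count `k` at or beyond the binomial mode `floor(w*m*p)` such
#' that the cluster probability falls below `1/N`, i.e. the cluster is rarer
#' than one expected occurrence in the accessible genome. Beyond the mode the
#' point probability is strictly decreasing in `k`, so the answer is unique.
#'
#' @inheritParams cluster_probability
#' @param N Accessible genome size in bp, or a name from
#'   [accessible_genome_sizes].
#' @return Minimum number of binding sites (integer).
#' @examples
#' min_sites_for_distinguishability(1000, 2e-3, "dnase_conservative")  # 13
#' min_sites_for_distinguishability(1000, 2e-3, "whole_genome")        # 15
#' @export
min_sites_for_distinguishability <- function(w, p, N, m = 1L) {
  N <- resolve_genome_size(N)
  check_cluster_domain(w, 0L, p, m, N)
  target <- log(1 / N)
  k <- floor(w * m * p)
  while (k <= w && stats::dbinom(k, w, m * p, log = TRUE) >= target) {
    k <- k + 1L
  }
  if (k > w) stop("no k <= w satisfies P(k) < 1/N for these parameters")
  as.integer(k)
}

#' Sweep the minimum-site calculation over a parameter grid
#'
#' Evaluates [min_sites_for_distinguishability] on the Cartesian product of
#' enhancer lengths, motif hit probabilities, and accessible genome sizes.
#'
#' @param w_values Enhancer lengths (bp).
#' @param p_values Motif hit probabilities.
#' @param N_values Accessible genome sizes (bp or names).
#' @param m Number of distinct TFs (single value).
#' @return A data frame with columns `w`, `p`, `N`, `m`, `k_min`, one row per
#'   combination.
#' @export
sweep_min_sites <- function(w_values, p_values, N_values, m = 1L) {
  stopifnot(length(w_values) >= 1, length(p_values) >= 1, length(N_values) >= 1)
  N_values <- vapply(N_values, resolve_genome_size, numeric(1))
  grid <- expand.grid(w = w_values, p = p_values, N = N_values,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$m <- as.integer(m)
  grid$k_min <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      min_sites_for_distinguishability(grid$w[i], grid$p[i], grid$N[i], m),
      error = function(e) {
        stop("sweep failed at (w=", grid$w[i], ", p=", grid$p[i],
             ", N=", grid$N[i], ", m=", m, "): ", conditionMessage(e),
             call. = FALSE)
      })
  }, integer(1))
  grid
}
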