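# shared fixtures, built in code at test time

uniform_bg <- function(N = "dnase_conservative") {
  background_model(q = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), N = N)
}

at_rich_bg <- function(N = "dnase_conservative") {
  background_model(q = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3), N = N)
}

# small deterministic count matrix: strong consensus ACGT + one mixed column
toy_counts <- function() {
  m <- matrix(c(10, 0, 0, 0,
                0, 10, 0, 0,
                0, 0, 10, 0,
                0, 0, 0, 10,
                4, 3, 2, 1), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# naive per-window score: the independent oracle for score_sequence
naive_window_score <- function(weights, window) {
  bases <- strsplit(window, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(weights[cbind(idx, seq_along(idx))])
}

# enumerate all 4^L windows: exact score distribution oracle
enumerate_score_distribution <- function(weights, q) {
  L <- ncol(weights)
  grids <- rev(expand.grid(rep(list(1:4), L)))
  scores <- apply(grids, 1, function(idx) sum(weights[cbind(idx, 1:L)]))
  probs <- apply(grids, 1, function(idx) prod(q[idx]))
  agg <- tapply(probs, round(scores, 10), sum)
  s <- as.numeric(names(agg))
  ord <- order(s)
  list(score = s[ord], prob = as.numeric(agg)[ord])
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
enumerate_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    ra <- rank(pooled)[idx_a]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
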