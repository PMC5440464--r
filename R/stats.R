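#' Five-number group summary with 1.5*IQR fences
#'
#' Quartiles use the linear-interpolation convention (R's default quantile
#' type 7); whiskers extend to `q1 - 1.5*IQR` and `q3 + 1.5*IQR`, and values
#' beyond the fences are reported as outliers.
#'
#' @param values Numeric vector, n >= 1.
#' @param label Group label.
#' @return Object of class `group_summary`: `group`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
group_summary <- function(values, label = "group") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input to group_summary")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr; hi <- qs[3] + 1.5 * iqr
  structure(list(group = label, n = length(values),
                 median = qs[2], q1 = qs[1], q3 = qs[3],
                 whisker_low = lo, whisker_high = hi,
                 outliers = values[values < lo | values > hi]),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n=%d median=%.4g [q1=%.4g, q3=%.4g] whiskers [%.4g, %.4g], %d outliers\n",
              x$group, x$n, x$median, x$q1, x$q3,
              x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}

summary_row <- function(s) {
  data.frame(group = s$group, n = s$n, median = s$median, q1 = s$q1,
             q3 = s$q3, whisker_low = s$whisker_low,
             whisker_high = s$whisker_high, n_outliers = length(s$outliers))
}

#' Per-group summaries of one metric
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @param group_order Optional ordering of the output rows.
#' @return Data frame, one [group_summary] row per group.
#' @export
summarize_groups <- function(values, groups, group_order = NULL) {
  labs <- if (is.null(group_order)) unique(groups) else group_order
  do.call(rbind, lapply(labs, function(g) {
    summary_row(group_summary(values[groups == g], g))
  }))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison, chosen because it
#' makes no normality assumption. The p-value is exact (full enumeration)
#' for tie-free samples with `min(n) <= 8`, and otherwise uses the normal
#' approximation with tie correction and continuity correction; the method
#' used is recorded in the result.
#'
#' @param a,b Numeric samples, each n >= 1.
#' @return List: `U` (the Mann-Whitney U of `a` vs `b`), `p_value`
#'   (two-sided), `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero rank variance (all observations tied): no evidence
  list(U = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "normal_approx",
       n_a = length(a), n_b = length(b))
}

#' All pairwise group comparisons of one metric
#'
#' Mann-Whitney tests between every unordered pair of groups, with
#' Bonferroni correction over the family of all pairs within this metric
#' (matching per-panel heatmap families). Groups with zero members are
#' excluded and reported.
#'
#' @param profiles Data frame of per-enhancer profiles (or any table).
#' @param metric Column of `profiles` to compare.
#' @param group_order Ordered group labels; ordering is taken from this
#'   argument, never from a lexical sort.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `U`, `p_value`, `p_adjusted`, `family_size`, `method`. The
#'   symmetric adjusted-p matrix is attached as attribute `p_matrix`, and
#'   excluded groups as attribute `excluded`.
#' @export
pairwise_comparisons <- function(profiles, metric, group_order = NULL) {
  stopifnot(metric %in% names(profiles))
  groups <- if (is.null(group_order)) unique(profiles$group) else group_order
  sizes <- vapply(groups, function(g) {
    sum(profiles$group == g & !is.na(profiles[[metric]]))
  }, integer(1))
  excluded <- groups[sizes == 0L]
  groups <- groups[sizes > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  pairs <- utils::combn(groups, 2L)
  fam <- ncol(pairs)
  rows <- lapply(seq_len(fam), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    va <- profiles[[metric]][profiles$group == ga]
    vb <- profiles[[metric]][profiles$group == gb]
    mw <- mann_whitney(va, vb)
    data.frame(group_a = ga, group_b = gb, n_a = mw$n_a, n_b = mw$n_b,
               U = mw$U, p_value = mw$p_value,
               p_adjusted = min(1, mw$p_value * fam),
               family_size = fam, method = mw$method)
  })
  out <- do.call(rbind, rows)
  pm <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  diag(pm) <- 1
  for (i in seq_len(nrow(out))) {
    pm[out$group_a[i], out$group_b[i]] <- out$p_adjusted[i]
    pm[out$group_b[i], out$group_a[i]] <- out$p_adjusted[i]
  }
  attr(out, "p_matrix") <- pm
  attr(out, "excluded") <- excluded
  out
}

#' Two-cohort comparison across architecture metrics
#'
#' Compares exactly two groups on each requested per-enhancer metric
#' (length, total sites, normalised sites, average motif hit probability)
#' with a two-sided Mann-Whitney test. Each metric is its own family of one
#' comparison, so `p_adjusted = p_value`.
#'
#' @param profiles Profile table from [profile_cohort] (`$profiles`).
#' @param metrics Metric columns to compare.
#' @return Data frame: one row per metric with group medians, `U`,
#'   `p_value`, `p_adjusted`, `family_size`, `method`.
#' @export
compare_two_cohorts <- function(profiles,
                                metrics = c("length_bp", "n_total",
                                            "normalized_sites", "p_av")) {
  groups <- unique(profiles$group)
  if (length(groups) != 2L) {
    stop("compare_two_cohorts needs exactly two groups, got ",
         length(groups), "; use pairwise_comparisons/run_stage_analysis for more")
  }
  missing <- setdiff(metrics, names(profiles))
  if (length(missing)) stop("metric(s) absent from profiles: ",
                            paste(missing, collapse = ", "))
  rows <- lapply(metrics, function(mname) {
    va <- profiles[[mname]][profiles$group == groups[1]]
    vb <- profiles[[mname]][profiles$group == groups[2]]
    mw <- mann_whitney(va, vb)
    data.frame(metric = mname, group_a = groups[1], group_b = groups[2],
               n_a = mw$n_a, n_b = mw$n_b,
               median_a = stats::median(va, na.rm = TRUE),
               median_b = stats::median(vb, na.rm = TRUE),
               U = mw$U, p_value = mw$p_value, p_adjusted = mw$p_value,
               family_size = 1L, method = mw$method)
  })
  do.call(rbind, rows)
}

#' Compare the specificity of two motif panels
#'
#' Mann-Whitney comparison of the per-TF motif hit probabilities (2^-I) of
#' two panels, the TF-level counterpart of the per-enhancer `p_av`
#' comparison. All TFs in each configured panel are included, whether or
#' not they hit any enhancer.
#'
#' @param calib_a,calib_b [calibrate_all] objects for the two panels.
#' @return One-row data frame like [compare_two_cohorts].
#' @export
compare_panel_specificity <- function(calib_a, calib_b) {
  pa <- motif_hit_probability(calib_a$info)
  pb <- motif_hit_probability(calib_b$info)
  mw <- mann_whitney(pa, pb)
  data.frame(metric = "tf_hit_probability", group_a = "panel_a",
             group_b = "panel_b", n_a = mw$n_a, n_b = mw$n_b,
             median_a = stats::median(pa), median_b = stats::median(pb),
             U = mw$U, p_value = mw$p_value, p_adjusted = mw$p_value,
             family_size = 1L, method = mw$method)
}
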