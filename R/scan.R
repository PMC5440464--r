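empty_hits <- function() {
  data.frame(enhancer_id = character(0), tf_name = character(0),
              offset = integer(0), strand = character(0),
              score = numeric(0), ln_pvalue = numeric(0))
}

# greedy non-overlapping pruning within one motif's hits, most significant first
prune_overlaps <- function(hits, width) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(hits$ln_pvalue, hits$offset, hits$strand)
  taken <- rep(FALSE, nrow(hits))
  occupied <- integer(0)
  for (i in ord) {
    span <- hits$offset[i]:(hits$offset[i] + width - 1L)
    if (!any(span %in% occupied)) {
      taken[i] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  hits[taken, , drop = FALSE]
}

#' Find calibrated binding-site hits in a sequence
#'
#' Scans an enhancer with every calibrated motif and reports each
#' window/strand whose ln(p-value) is at or below that motif's cutoff. All
#' qualifying positions are reported (overlaps permitted) unless
#' `non_overlapping = TRUE`, which keeps a greedy most-significant-first
#' non-overlapping subset per motif. A site passing on both strands at one
#' offset counts twice (palindromes can double-count). Windows containing
#' non-ACGT characters are never scored. An enhancer shorter than every
#' motif yields an empty hit table, not an error.
#'
#' @param sequence DNA string.
#' @param calibration A [calibrate_all] object.
#' @param strands `"both"` or `"forward"`; defaults to the strands the
#'   calibration was built with.
#' @param enhancer_id Identifier recorded in the output.
#' @param non_overlapping Prune overlapping hits per motif (default FALSE).
#' @return Data frame with columns `enhancer_id`, `tf_name`, `offset`
#'   (0-based), `strand`, `score` (bits, discretised to the scoring bin
#'   grid), `ln_pvalue`; ordered by (offset, tf_name, strand).
#' @export
find_hits <- function(sequence, calibration, strands = NULL,
                      enhancer_id = "enhancer", non_overlapping = FALSE) {
  stopifnot(inherits(calibration, "motif_calibration"))
  if (is.null(strands)) strands <- calibration$strands
  ints <- encode_dna(sequence)
  out <- list()
  for (tf in names(calibration$pwms)) {
    sdist <- calibration$sdists[[tf]]
    L <- ncol(sdist$iweights)
    if (length(ints) < L) next
    cutoff <- calibration$cutoffs[[tf]]
    sc <- window_iscores(ints, sdist, strands)
    hits <- list()
    for (st in c("+", "-")) {
      v <- if (st == "+") sc$fwd else sc$rev
      if (is.null(v)) next
      lnp <- ln_tail_at_bin(sdist, v)
      pass <- which(!is.na(v) & lnp <= cutoff)
      if (length(pass)) {
        hits[[st]] <- data.frame(
          enhancer_id = enhancer_id, tf_name = tf,
          offset = pass - 1L, strand = st,
          score = v[pass] * sdist$bin_width, ln_pvalue = lnp[pass])
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
    if (non_overlapping) hits <- prune_overlaps(hits, L)
    out[[tf]] <- hits
  }
  out <- if (length(out)) do.call(rbind, out) else empty_hits()
  out <- out[order(out$offset, out$tf_name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Architecture profile of one enhancer
#'
#' Summarises an enhancer's hit table into the per-enhancer quantities the
#' analysis compares across groups: total site count, site count normalised
#' by the number of motifs searched (including motifs with zero hits, so
#' groups with different TF repertoires are comparable), and the average
#' motif hit probability `p_av` over the TFs that hit the enhancer.
#'
#' @param enhancer_id,group,length_bp Enhancer identity and length.
#' @param hits Hit table from [find_hits] for this enhancer.
#' @param calibration The [calibrate_all] object used for scanning (supplies
#'   the motifs-searched denominator and per-TF information contents).
#' @return One-row data frame: `enhancer_id`, `group`, `length_bp`,
#'   `n_total`, `n_motifs_searched`, `normalized_sites`, `p_av` (`NA` when
#'   the enhancer has no hits). Per-TF counts are attached as attribute
#'   `per_tf_counts` (named integer vector over all motifs searched).
#' @export
profile_enhancer <- function(enhancer_id, group, length_bp, hits, calibration) {
  stopifnot(inherits(calibration, "motif_calibration"))
  tfs <- names(calibration$pwms)
  if (length(tfs) == 0L) stop("empty motif list")
  if (nrow(hits) > 0 && !all(hits$enhancer_id == enhancer_id)) {
    stop("hit table contains rows for a different enhancer")
  }
  n_j <- table(factor(hits$tf_name, levels = tfs))
  n_j <- stats::setNames(as.integer(n_j), tfs)
  n_total <- sum(n_j)
  p_av <- if (n_total > 0) {
    average_motif_hit_probability(n_j[n_j > 0], calibration$info[names(n_j)[n_j > 0]])
  } else NA_real_
  out <- data.frame(enhancer_id = enhancer_id, group = group,
                    length_bp = length_bp, n_total = n_total,
                    n_motifs_searched = length(tfs),
                    normalized_sites = n_total / length(tfs),
                    p_av = p_av)
  attr(out, "per_tf_counts") <- n_j
  out
}

#' Profile an enhancer cohort
#'
#' Scans every enhancer with the motif panel of its own group and profiles
#' it. Each group can carry its own calibrated panel (as for stage-resolved
#' analyses, where the `normalized_sites` denominator must be the stage's
#' own motif count); a single calibration is applied to all groups.
#' Enhancers whose group has no motif panel are reported as unprofiled and
#' the run continues.
#'
#' @param enhancers Data frame with columns `id`, `group`, `sequence` (and
#'   optionally `length_bp`), e.g. from [read_enhancers] or
#'   [generate_cohort].
#' @param calibrations Either one [calibrate_all] object for all groups, or
#'   a named list of them keyed by group label.
#' @param strands,non_overlapping Passed to [find_hits].
#' @return List with `profiles` (one row per profiled enhancer), `hits`
#'   (all hits), `per_tf_counts` (long data frame enhancer x TF), and
#'   `unprofiled` (ids and reasons).
#' @export
profile_cohort <- function(enhancers, calibrations, strands = NULL,
                           non_overlapping = FALSE) {
  stopifnot(is.data.frame(enhancers),
            all(c("id", "group", "sequence") %in% names(enhancers)))
  single <- inherits(calibrations, "motif_calibration")
  profiles <- list(); hits <- list(); counts <- list(); unprof <- list()
  for (i in seq_len(nrow(enhancers))) {
    id <- enhancers$id[i]; grp <- enhancers$group[i]
    calib <- if (single) calibrations else calibrations[[grp]]
    if (is.null(calib)) {
      unprof[[length(unprof) + 1L]] <- data.frame(
        id = id, group = grp, reason = "no motif panel for group")
      next
    }
    seq <- enhancers$sequence[i]
    w <- if ("length_bp" %in% names(enhancers)) enhancers$length_bp[i] else nchar(seq)
    h <- find_hits(seq, calib, strands, enhancer_id = id,
                   non_overlapping = non_overlapping)
    pr <- profile_enhancer(id, grp, w, h, calib)
    n_j <- attr(pr, "per_tf_counts")
    counts[[length(counts) + 1L]] <- data.frame(
      enhancer_id = id, group = grp, tf_name = names(n_j), n = unname(n_j))
    profiles[[length(profiles) + 1L]] <- pr
    hits[[length(hits) + 1L]] <- h
  }
  if (length(profiles) == 0L) stop("no enhancer could be profiled")
  list(profiles = do.call(rbind, profiles),
       hits = do.call(rbind, hits),
       per_tf_counts = do.call(rbind, counts),
       unprofiled = if (length(unprof)) do.call(rbind, unprof) else NULL)
}

as_granges <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end (0-based half-open)")
  chrom <- if ("chrom" %in% names(x)) x$chrom else "chr"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Fraction of intervals overlapping another interval set
#'
#' For two sets of genomic intervals (0-based half-open, shared assembly),
#' returns the fraction of intervals in `a` overlapping at least 1 bp of
#' some interval in `b`, plus each interval's best overlap length as a
#' fraction of the shorter of the two intervals involved.
#'
#' @param a,b Data frames with columns `chrom` (optional), `start`, `end`.
#' @return List: `fraction` (scalar), `per_interval` (data frame with the
#'   best overlap fraction per interval of `a`; 0 when disjoint).
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L) stop("empty query interval set")
  ga <- as_granges(a); gb <- as_granges(b)
  # disjoint chromosome sets are a legitimate query, not a user error
  ov <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L))
  frac <- rep(0, length(ga))
  if (length(ov)) {
    qa <- ga[S4Vectors::queryHits(ov)]
    qb <- gb[S4Vectors::subjectHits(ov)]
    inter <- GenomicRanges::width(GenomicRanges::pintersect(qa, qb))
    shorter <- pmin(GenomicRanges::width(qa), GenomicRanges::width(qb))
    best <- tapply(inter / shorter, S4Vectors::queryHits(ov), max)
    frac[as.integer(names(best))] <- as.numeric(best)
  }
  list(fraction = mean(frac > 0),
       per_interval = data.frame(index = seq_len(nrow(a)),
                                 best_overlap_fraction = frac))
}
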