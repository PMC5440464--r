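calibrations_for_groups <- function(panels, background, percentile, strands,
                                    bin_width = 0.01) {
  out <- lapply(panels, function(p) {
    calibrate_all(p, background, percentile, strands, bin_width)
  })
  names(out) <- names(panels)
  out
}

write_bundle <- function(res, out_dir, widths) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$profiles, file.path(out_dir, "profiles.tsv"))
  write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
  write_hits_bed(res$hits, widths, file.path(out_dir, "hits.bed"))
  write_tsv(res$summaries, file.path(out_dir, "summaries.tsv"))
  write_tsv(res$comparisons, file.path(out_dir, "comparisons.tsv"))
  write_tsv(res$cutoffs, file.path(out_dir, "cutoffs.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

panel_widths <- function(calibs) {
  w <- unlist(lapply(calibs, function(cl) {
    vapply(cl$pwms, function(p) p$width, numeric(1))
  }))
  names(w) <- sub("^[^.]*\\.", "", names(w))
  w[!duplicated(names(w))]
}

profile_metrics <- c("length_bp", "n_total", "normalized_sites", "p_av")

#' Two-group axis-style architecture comparison
#'
#' The full pipeline for comparing two enhancer cohorts (e.g. AP vs DV):
#' calibrates each group's motif panel on its training alignments, scans
#' every enhancer with its group's panel, profiles the hits, and compares
#' the groups on length, total binding sites, sites normalised per motif
#' searched, and average motif hit probability (plus the TF-level panel
#' specificity comparison) with two-sided Mann-Whitney tests.
#'
#' @param enhancers Data frame (`id`, `group`, `sequence`, optionally
#'   `length_bp`) with exactly two groups.
#' @param panels Named list (by group label) of PWM lists; or a single PWM
#'   list applied to both groups.
#' @param background A [background_model].
#' @param percentile Calibration percentile (default 75).
#' @param strands `"both"` or `"forward"`.
#' @param out_dir Optional directory for the report bundle (profiles,
#'   hits TSV + BED6, summaries, comparisons, cutoffs, manifest.json).
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List: `profiles`, `hits`, `summaries` (per group x metric),
#'   `comparisons` (per metric + TF specificity), `cutoffs`,
#'   `calibrations`, `unprofiled`, `manifest`.
#' @export
run_axis_analysis <- function(enhancers, panels, background,
                              percentile = 75, strands = c("both", "forward"),
                              out_dir = NULL, seed = NULL) {
  strands <- match.arg(strands)
  groups <- unique(enhancers$group)
  if (length(groups) != 2L) {
    stop("axis analysis needs exactly two groups (got ", length(groups),
         "); use run_stage_analysis for ordered multi-group cohorts")
  }
  if (!is.null(names(panels)) && all(groups %in% names(panels))) {
    panels <- panels[groups]
  } else if (all(vapply(panels, inherits, logical(1), "pwm"))) {
    panels <- stats::setNames(list(panels, panels), groups)
  } else {
    stop("panels must be a named list covering groups: ",
         paste(groups, collapse = ", "))
  }
  calibs <- calibrations_for_groups(panels, background, percentile, strands)
  prof <- profile_cohort(enhancers, calibs)
  summaries <- do.call(rbind, lapply(profile_metrics, function(mname) {
    s <- summarize_groups(prof$profiles[[mname]], prof$profiles$group, groups)
    cbind(metric = mname, s)
  }))
  comparisons <- rbind(
    compare_two_cohorts(prof$profiles),
    local({
      sp <- compare_panel_specificity(calibs[[groups[1]]], calibs[[groups[2]]])
      sp$group_a <- groups[1]; sp$group_b <- groups[2]
      sp
    }))
  cutoffs <- do.call(rbind, lapply(groups, function(g) {
    cbind(group = g, calibs[[g]]$table)
  }))
  manifest <- run_manifest(
    params = list(analysis = "axis", percentile = percentile,
                  strands = strands, seed = seed,
                  groups = as.list(groups)),
    counts = list(enhancers = nrow(enhancers),
                  profiled = nrow(prof$profiles),
                  motifs = vapply(calibs, function(cl) length(cl$pwms), integer(1)),
                  hits = nrow(prof$hits),
                  training_skipped = sum(cutoffs$n_training_skipped)))
  res <- list(profiles = prof$profiles, hits = prof$hits,
              summaries = summaries, comparisons = comparisons,
              cutoffs = cutoffs, calibrations = calibs,
              unprofiled = prof$unprofiled, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(res, out_dir, panel_widths(calibs))
  res
}

#' Stage-resolved architecture trend analysis
#'
#' Profiles an ordered multi-group cohort (e.g. developmental stage
#' intervals) with per-stage motif panels, summarises each stage on the
#' four architecture metrics, and computes Bonferroni-adjusted pairwise
#' Mann-Whitney matrices for enhancer length and normalised binding-site
#' count. Stage order is taken from `stage_order`, never sorted. Stages
#' with zero enhancers are dropped and reported.
#'
#' @param enhancers Data frame (`id`, `group`, `sequence`).
#' @param panels Named list of PWM lists keyed by stage label.
#' @param background A [background_model].
#' @param stage_order Ordered stage labels (default: order of `panels`).
#' @inheritParams run_axis_analysis
#' @return List: `profiles`, `hits`, `summaries`, `pairwise` (named list of
#'   comparison tables with `p_matrix` attributes for `length_bp` and
#'   `normalized_sites`), `cutoffs`, `calibrations`, `dropped_stages`,
#'   `unprofiled`, `manifest`.
#' @export
run_stage_analysis <- function(enhancers, panels, background,
                               stage_order = names(panels),
                               percentile = 75,
                               strands = c("both", "forward"),
                               out_dir = NULL, seed = NULL) {
  strands <- match.arg(strands)
  if (length(stage_order) < 2L) stop("need >= 2 ordered stages")
  present <- stage_order[stage_order %in% enhancers$group]
  dropped <- setdiff(stage_order, present)
  if (length(present) < 2L) stop("fewer than 2 stages have enhancers")
  calibs <- calibrations_for_groups(panels[present], background,
                                    percentile, strands)
  prof <- profile_cohort(enhancers[enhancers$group %in% present, , drop = FALSE],
                         calibs)
  summaries <- do.call(rbind, lapply(profile_metrics, function(mname) {
    s <- summarize_groups(prof$profiles[[mname]], prof$profiles$group, present)
    cbind(metric = mname, s)
  }))
  pairwise <- lapply(c(length_bp = "length_bp",
                       normalized_sites = "normalized_sites"),
                     function(mname) {
                       pairwise_comparisons(prof$profiles, mname, present)
                     })
  cutoffs <- do.call(rbind, lapply(present, function(g) {
    cbind(group = g, calibs[[g]]$table)
  }))
  manifest <- run_manifest(
    params = list(analysis = "stage_trend", percentile = percentile,
                  strands = strands, seed = seed,
                  stage_order = as.list(present)),
    counts = list(enhancers = nrow(enhancers),
                  profiled = nrow(prof$profiles),
                  dropped_stages = length(dropped),
                  hits = nrow(prof$hits)))
  res <- list(profiles = prof$profiles, hits = prof$hits,
              summaries = summaries, pairwise = pairwise,
              cutoffs = cutoffs, calibrations = calibs,
              dropped_stages = dropped, unprofiled = prof$unprofiled,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res$profiles, file.path(out_dir, "profiles.tsv"))
    write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
    write_tsv(res$summaries, file.path(out_dir, "summaries.tsv"))
    for (mname in names(pairwise)) {
      write_tsv(pairwise[[mname]],
                file.path(out_dir, paste0("pairwise_", mname, ".tsv")))
    }
    write_tsv(cutoffs, file.path(out_dir, "cutoffs.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
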