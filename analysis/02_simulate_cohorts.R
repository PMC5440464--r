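#!/usr/bin/env Rscript
# Generates the two synthetic study cohorts with planted binding sites:
#  - a two-group axis-patterning-like cohort (complex-task group: 60
#    enhancers, median 1300 bp, ~47 sites over 24 motifs; simpler-task
#    group: 39 enhancers, 800 bp, ~9 sites over 10 motifs), and
#  - a six-stage cohort whose median enhancer length declines over
#    developmental time.
# Every file the downstream drivers consume is written under
# results/cohorts/, together with the planted-site truth tables.

suppressMessages(library(enhancerarch))

seed <- 1L
axis <- generate_cohort(ap_dv_cohort_spec(seed = seed),
                        dir = "results/cohorts/axis")
stage <- generate_cohort(stage_cohort_spec(seed = seed + 1L),
                         dir = "results/cohorts/stage")

for (coh in list(axis, stage)) {
  tab <- table(coh$enhancers$group)
  med <- tapply(coh$enhancers$length_bp, coh$enhancers$group, median)
  cat(sprintf("cohort [%s]: %d enhancers, %d planted sites\n",
              paste(names(tab), collapse = ", "),
              nrow(coh$enhancers), nrow(coh$truth)))
  for (g in names(tab)) {
    cat(sprintf("  %-6s n = %2d, median length = %4.0f bp\n",
                g, tab[[g]], med[[g]]))
  }
}
cat("written under results/cohorts/ (FASTA, groups.tsv, motif matrices,\n",
    "training alignments, truth tables, config.json)\n")
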