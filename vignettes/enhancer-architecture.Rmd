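---
title: "Enhancer architecture and regulatory task complexity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer architecture and regulatory task complexity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerarch)
```

## The question

Enhancers drive spatiotemporal gene expression by clustering transcription
factor (TF) binding sites, and they vary enormously in length, site number,
and the binding specificity of the TFs they recruit. This package implements
a quantitative framework for asking whether the *complexity of an enhancer's
regulatory task* — how many cell fates are being specified at once — shapes
that architecture. It provides four connected layers:

1. a binomial model of when a cluster of binding sites is distinguishable
   from genomic background;
2. position weight matrix (PWM) scanning with exact background score
   distributions and principled, training-set-calibrated thresholds;
3. information-content-based specificity statistics per motif and per
   enhancer; and
4. nonparametric group comparisons (Mann-Whitney with Bonferroni
   correction) over per-enhancer architecture profiles,

together with a synthetic-cohort generator that plants known binding sites
so every downstream property can be validated against ground truth.

## The distinguishability model

Treat each position of an enhancer of length $w$ bp as an independent
Bernoulli trial in which a motif hit occurs with probability $p$. The
probability of exactly $k$ hits is the binomial point mass

$$P(k) = \binom{w}{k} p^k (1-p)^{w-k},$$

and when the cluster mixes sites of $m$ TFs with identical hit probability,
$p$ is replaced by $mp$. A cluster is *distinguishable* from background when
it is rarer than one expected occurrence in the accessible genome of $N$ bp:
$P(k) < 1/N$. `min_sites_for_distinguishability()` returns the smallest
$k$ at or beyond the distribution's mode $\lfloor wmp \rfloor$ that
satisfies this; beyond the mode $P(k)$ is strictly decreasing, so the
answer is unique. We read $P(k)$ as the point mass (not the upper tail):
this reading reproduces both published anchor values below, and the mode
restriction keeps the criterion meaningful on the rare-event side of the
distribution.

```{r anchors}
min_sites_for_distinguishability(1000, 2e-3, "dnase_conservative")  # 13
min_sites_for_distinguishability(1000, 2e-3, "whole_genome")        # 15
```

Probabilities are computed in log space (`dbinom(log = TRUE)`), safe for
$w$ up to $10^5$ and probabilities down to $10^{-300}$; a guard rejects
$w > 10^6$ to bound the linear $k$ search. The three shipped genome sizes
(`accessible_genome_sizes`) are a conservative DNase-hypersensitivity
estimate (4.1 Mb), a relaxed one (19.4 Mb), and the whole genome
(175.5 Mb); they are constants of the analysis, not re-derived from
chromatin data.

Two numerical notes. The binomial-to-Poisson approximation
$P(k) \approx e^{-\lambda}\lambda^k/k!$ with $\lambda = wmp$ has relative
error growing like $k^2/2w$, so it is a few-percent approximation only
when $w$ is well above $k^2$; our tests exercise it at $w = 10^4$. And
under the constraint $N \ge w$ the mode itself essentially never satisfies
$P(\text{mode}) < 1/N$ for realistic $w$, so the returned $k$ is in
practice strictly beyond the mode.

## PWM construction, scoring, and exact p-values

A PWM stores per-position base frequencies $p_i(b)$. `build_pwm()` accepts
a count matrix or an aligned set of binding sites and adds pseudocounts *in
proportion to the background frequency of each base*, to a total mass of
0.01 per column:

$$p_i(b) = \frac{c_i(b) + 0.01\,q(b)}{C_i + 0.01}.$$

We interpret "a total of 0.01" as per-column mass (the quantity
Patser-style tools normalise); the `pseudocount_total` argument makes the
per-matrix reading available if wanted. Scoring uses the log-odds weights
$\log_2 p_i(b)/q(b)$ in bits, summed over a window.

The p-value of a window score is computed exactly under the background
model: weights are discretised to a 0.01-bit grid and convolved
position-by-position (the Staden / Hertz–Stormo dynamic program), giving
the full distribution of scores at a random background position and hence
$\ln P(\text{score} \ge s)$ for every achievable $s$. Scanning
(`find_hits()`) scores windows with the *same* discretised weights, so a
hit's reported ln(p-value) is exactly the distribution's tail value — the
background hit rate at a cutoff then matches the tail probability as an
identity, not an approximation. The cost is that reported scores are
rounded to the bin grid (at most 0.005 bits per position); tests quantify
the induced error against exhaustive $4^L$ enumeration for short motifs.

Conventions: both strands are scanned by default (reverse-strand windows
are scored on their reverse complement and reported at forward
coordinates, 0-based half-open, BED-compatible). One background score
distribution serves both strands; that is exact when the background
composition is complement-symmetric, which the package default
$q = (0.3, 0.2, 0.2, 0.3)$ — AT-rich, Drosophila-intergenic-like — is.
Windows containing non-ACGT characters are skipped rather than scored
worst-case, which can only lose hits, never fabricate them. Overlapping
hits and palindromic double-counting are kept by default (no pruning rule
is assumed); `non_overlapping = TRUE` applies a greedy
most-significant-first filter.

## Cutoff calibration on training alignments

Rather than a fixed score threshold per motif, `calibrate_cutoff()` scores
the motif's *own training alignment* and sets the cutoff so that a chosen
percentage (default 75%) of training sequences qualify as true sites. Each
training sequence gets its best (smallest) ln(p-value) over offsets and
strands; the cutoff is the nearest-rank 75th order statistic of these
values in ascending order. ln(p-values) are negative with more-negative =
more significant, so this is the only direction under which "75% of the
aligned sequences are considered true" holds; ties are included, so the
pass-rate guarantee is $\ge$ the percentile by construction. Sequences
shorter than the motif cannot be scored and are counted as skipped —
silently dropping them would bias the order statistic. `calibrate_all()`
applies this across a panel and reports unusable motifs instead of
dropping them.

## Specificity statistics

Motif specificity is the Kullback-Leibler information content

$$I = \sum_{i=1}^{L}\sum_{b} p_i(b)\log_2\frac{p_i(b)}{q(b)} \quad
\text{(bits)},$$

and $p = 2^{-I}$ approximates the probability of a motif hit at a random
background position. At the enhancer level, the site-count-weighted
average

$$p_{av} = \frac{\sum_j n_j 2^{-I_j}}{\sum_j n_j}$$

summarises the average specificity of the TFs *actually hitting* the
enhancer ($n_j$ = sites for TF $j$). It is undefined (reported `NA`, never
silently 0) for an enhancer with no hits. The per-enhancer profile also
records the total site count and the count normalised by the number of
motifs *searched* — including motifs with zero hits — which is what makes
groups scanned with different-sized TF repertoires comparable.

## Group comparisons

All distribution comparisons use the two-sided Mann-Whitney rank-sum test
(no normality assumption): exact enumeration for tie-free samples with
$\min(n) \le 8$, normal approximation with tie and continuity correction
otherwise, with the method recorded. When the rank variance is zero (all
pooled values tied) the test carries no evidence and p = 1 is reported.
Families of multiple comparisons are Bonferroni-corrected; the family is
all group pairs *within one metric* (each pairwise heatmap is its own
family), so a two-group comparison has a family of one. Box summaries use
linear-interpolation quartiles (R's default type 7 — the convention is
recorded because medians of small samples can shift one position under
other conventions) and 1.5·IQR whisker fences.

## The synthetic cohort generator

`generate_cohort()` builds everything the pipeline consumes, from a single
seed: motif panels of controlled information content, training alignments,
background sequence of specified composition, and enhancer groups with
planted sites.

* **Motifs** (`generate_pwm()`): each column is a mixture
  $\alpha\,e_{\text{consensus}} + (1-\alpha)\,q$ with a random consensus
  base; one $\alpha$ is solved by root-finding so the realised
  (pseudocounted) information content lands within 0.1 bits of target.
  Training sites are *sampled from the PWM*, not consensus copies, so
  calibration's order statistics see realistic score spread.
* **Enhancers** (`generate_enhancer()`): lengths are log-normal
  (positive, right-skewed, as real enhancer lengths are), planted-site
  counts Poisson, placements uniform-random without overlap (sorted-gap
  construction), strands uniform. The planted truth table is a first-class
  output: every recovery property is measured against it.
* **Study conditions**: the default two-group spec
  (`ap_dv_cohort_spec()`) mirrors the axis-patterning cohorts — group AP:
  60 enhancers, median 1300 bp, ~47 planted sites over a 24-motif panel;
  group DV: 39 enhancers, 800 bp, ~9 sites over 10 motifs. Values the
  study design does not fix were chosen once as field-realistic and left
  alone: length log-SD 0.4, motif widths cycling 8/10/12 bp, panel
  information contents spanning 6.5–9 bits (AP) and 7–10 bits (DV),
  bracketing per-TF hit probabilities around $10^{-3}$–$10^{-2}$. Planted
  counts are capped at 60% sequence coverage so short length draws remain
  packable (real complex-task enhancers run ~35% site coverage; the cap
  binds only in the short tail). The six-stage spec
  (`stage_cohort_spec()`) declines in median length from 1100 to 450 bp
  with per-stage panels of 8–14 motifs.

What the generator does *not* emulate: positional clustering or spacing
constraints between sites, dinucleotide or higher-order background
structure, overlapping/competing sites, and TF-TF cooperativity. Passing
tests therefore demonstrate that the *measurement machinery* is correct
and that planted contrasts are recovered — not that real enhancers satisfy
the binomial independence assumptions.

## Problem sizes and determinism

The shipped analyses and tests run at deliberately modest scale: cohorts
of ~100–150 enhancers, panels of 1–24 motifs of width ≤ 12, background
sequences of $10^5$ bp for hit-rate checks, and 1000 replicates for the
type-I-error simulation — sizes at which every property being asserted is
already well-resolved. All generation flows through per-object integer
seeds, so cohorts are bit-reproducible across runs and platforms; the
scanning and statistics layers are fully deterministic.

## Known limitations

* The distinguishability model assumes independent positions and a single
  effective hit probability; it is a null model for rarity, not a
  thermodynamic occupancy model.
* $p = 2^{-I}$ is a first-order approximation to the true hit probability
  at a calibrated threshold; the two are compared explicitly in the
  background hit-rate tests.
* One score distribution serves both strands, exact only for
  complement-symmetric backgrounds (the default is; user-supplied
  compositions may not be).
* Motif selection per TF (when several matrices exist) uses the
  largest-training-alignment rule with a per-TF override map; no curation
  logic beyond that is attempted.
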