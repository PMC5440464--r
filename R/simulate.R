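# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a PWM of controlled information content
#'
#' Builds a synthetic motif whose (pseudocounted) information content hits a
#' target to within 0.1 bits, together with a training alignment sampled
#' from it. Each column is a mixture `alpha * consensus + (1 - alpha) * q`
#' with a random consensus base; a single mixing weight `alpha` is solved by
#' root-finding so that the realised information content matches the target.
#'
#' @param width Motif length in positions.
#' @param target_I Target information content in bits; must be feasible for
#'   this width and background (at most about `2 * width` for uniform
#'   background, less for skewed compositions).
#' @param background A [background_model].
#' @param seed Integer seed; the generator is fully reproducible.
#' @param n_train Number of training sequences to sample (default 50).
#' @param pseudocount_total Passed to [build_pwm].
#' @param name TF identifier.
#' @return A [build_pwm] object with training alignment attached; the
#'   mixture frequencies used for sampling are stored as attribute
#'   `sampling_freqs` and the target as `target_I`.
#' @export
generate_pwm <- function(width, target_I, background, seed,
                         n_train = 50L, pseudocount_total = 0.01,
                         name = "synthTF") {
  stopifnot(width >= 1, target_I >= 0)
  q <- background$q
  with_seed(seed, {
    cons <- sample(1:4, width, replace = TRUE)
    E <- matrix(0, 4, width); E[cbind(cons, seq_len(width))] <- 1
    ic_at <- function(alpha) {
      f <- alpha * E + (1 - alpha) * q
      p <- sweep(f + pseudocount_total * q, 2L, 1 + pseudocount_total, "/")
      sum(p * log2(sweep(p, 1L, q, "/")))
    }
    max_I <- ic_at(1)
    if (target_I > max_I - 0.05) {
      stop(sprintf("target_I = %.2f bits infeasible for width %d (max %.2f)",
                   target_I, width, max_I))
    }
    alpha <- if (target_I == 0) 0 else {
      stats::uniroot(function(a) ic_at(a) - target_I, c(0, 1),
                     tol = 1e-8)$root
    }
    f <- alpha * E + (1 - alpha) * q
    train <- vapply(seq_len(n_train), function(i) {
      decode_dna(apply(f, 2L, function(col) sample.int(4L, 1L, prob = col)))
    }, character(1))
    pwm <- build_pwm(f, background, pseudocount_total, name = name,
                     training = train)
    attr(pwm, "sampling_freqs") <- f
    attr(pwm, "target_I") <- target_I
    pwm
  })
}

#' Generate i.i.d. background sequence
#'
#' @param length Sequence length in bp.
#' @param background A [background_model] giving the composition.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
generate_background <- function(length, background, seed) {
  stopifnot(length >= 1)
  with_seed(seed,
    paste(sample(DNA_BASES, length, replace = TRUE, prob = background$q),
          collapse = ""))
}

#' Generate one enhancer with planted binding sites
#'
#' Produces a background sequence with `n_sites` motif instances planted at
#' uniformly random non-overlapping positions. Each site is sampled from its
#' PWM's column distributions (not consensus-only, so downstream
#' calibration behaves as it would on real sites) and placed on a uniformly
#' chosen strand (reverse-strand sites are inserted as the reverse
#' complement).
#'
#' @param length Enhancer length in bp.
#' @param panel Named list of [build_pwm] objects (or objects from
#'   [generate_pwm], whose `sampling_freqs` attribute is then used).
#' @param n_sites Either a single total site count (TFs drawn uniformly from
#'   the panel) or a named vector of per-TF counts.
#' @param background A [background_model].
#' @param seed Integer seed.
#' @param id,group Identity recorded in the outputs.
#' @return List: `record` (one-row data frame `id`, `group`, `sequence`,
#'   `length_bp`) and `truth` (data frame of planted sites: `enhancer_id`,
#'   `tf_name`, `offset` 0-based, `strand`, `site` as motif-strand
#'   sequence).
#' @export
generate_enhancer <- function(length, panel, n_sites, background, seed,
                              id = "enh", group = "grp") {
  stopifnot(length >= 1, length(panel) >= 1)
  if (is.null(names(panel))) {
    names(panel) <- vapply(panel, function(p) p$name, character(1))
  }
  with_seed(seed, {
    if (!is.null(names(n_sites))) {
      bad <- setdiff(names(n_sites), names(panel))
      if (length(bad)) stop("unknown TF(s) in site plan: ", paste(bad, collapse = ", "))
      tf_draw <- rep(names(n_sites), times = n_sites)
    } else {
      tf_draw <- if (n_sites > 0) {
        sample(names(panel), n_sites, replace = TRUE)
      } else character(0)
    }
    k <- length(tf_draw)
    widths <- vapply(tf_draw, function(tf) panel[[tf]]$width, numeric(1))
    if (sum(widths) > length) {
      stop(sprintf("cannot pack %d sites (%d bp of motif) into %d bp",
                   k, sum(widths), length))
    }
    bg <- sample(DNA_BASES, length, replace = TRUE, prob = background$q)
    truth <- data.frame(enhancer_id = character(0), tf_name = character(0),
                        offset = integer(0), strand = character(0),
                        site = character(0))
    if (k > 0) {
      ord <- sample.int(k)            # random interleaving of TFs
      tf_draw <- tf_draw[ord]; widths <- widths[ord]
      free <- length - sum(widths)
      u <- sort(stats::runif(k))
      starts <- floor(u * free) + cumsum(c(0, widths[-k]))  # 0-based
      rows <- vector("list", k)
      for (i in seq_len(k)) {
        pwm <- panel[[tf_draw[i]]]
        f <- attr(pwm, "sampling_freqs")
        if (is.null(f)) f <- pwm$freqs
        site_ints <- apply(f, 2L, function(col) sample.int(4L, 1L, prob = col))
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") site_ints else revcomp_ints(site_ints)
        bg[(starts[i] + 1):(starts[i] + widths[i])] <- DNA_BASES[ins]
        rows[[i]] <- data.frame(enhancer_id = id, tf_name = tf_draw[i],
                                offset = as.integer(starts[i]), strand = strand,
                                site = decode_dna(site_ints))
      }
      truth <- do.call(rbind, rows)
      truth <- truth[order(truth$offset), , drop = FALSE]
      rownames(truth) <- NULL
    }
    list(record = data.frame(id = id, group = group,
                             sequence = paste(bg, collapse = ""),
                             length_bp = length),
         truth = truth)
  })
}

#' Specification of a synthetic enhancer cohort
#'
#' @param groups List of group specs, each a list with `label`,
#'   `n` (enhancers), `length_median` and `length_log_sd` (log-normal length
#'   distribution, bp), `sites_mean` (Poisson mean planted sites per
#'   enhancer), and `panel` (data frame with columns `name`, `width`,
#'   `target_I` describing the group's motif panel).
#' @param q Background base composition (A, C, G, T).
#' @param N Accessible genome size.
#' @param seed Integer seed recorded in every output.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, q = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                        N = "dnase_conservative", seed = 1L) {
  for (g in groups) {
    stopifnot(all(c("label", "n", "length_median", "length_log_sd",
                    "sites_mean", "panel") %in% names(g)),
              g$n >= 1, g$length_median > 0, g$length_log_sd >= 0,
              g$sites_mean >= 0,
              all(c("name", "width", "target_I") %in% names(g$panel)))
  }
  structure(list(groups = groups, background = background_model(q, N),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

panel_spec <- function(prefix, n, widths = c(8L, 10L, 12L),
                       I_range = c(7, 10)) {
  data.frame(name = sprintf("%s%02d", prefix, seq_len(n)),
             width = rep(widths, length.out = n),
             target_I = seq(I_range[1], I_range[2], length.out = n))
}

#' Default two-group axis-patterning-like cohort specification
#'
#' Emulates the structure of the early embryonic axis-patterning cohorts:
#' a complex-task group ("AP": 60 enhancers, log-normal median length
#' 1300 bp, ~47 planted sites per enhancer over a 24-motif panel of
#' lower-specificity TFs, 6.5-9 bits) and a simpler-task group ("DV": 39
#' enhancers, median 800 bp, ~9 sites over a 10-motif panel of
#' higher-specificity TFs, 7-10 bits).
#'
#' @param seed Integer seed.
#' @return A [cohort_spec].
#' @export
ap_dv_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    groups = list(
      list(label = "AP", n = 60L, length_median = 1300, length_log_sd = 0.4,
           sites_mean = 47, panel = panel_spec("apTF", 24L, I_range = c(6.5, 9))),
      list(label = "DV", n = 39L, length_median = 800, length_log_sd = 0.4,
           sites_mean = 9, panel = panel_spec("dvTF", 10L, I_range = c(7, 10)))),
    seed = seed)
}

#' Stage-resolved cohort specification with a monotone length trend
#'
#' Six developmental-stage groups whose median enhancer length decreases
#' monotonically, emulating the declining regulatory task complexity over
#' embryogenesis; per-stage motif panels differ in size.
#'
#' @param seed Integer seed.
#' @param n_per_stage Enhancers per stage.
#' @return A [cohort_spec]; the stage order is the order of `groups`.
#' @export
stage_cohort_spec <- function(seed = 1L, n_per_stage = 25L) {
  stages <- c("4-6", "7-8", "9-10", "11-12", "13-14", "15-16")
  medians <- c(1100, 1000, 850, 700, 550, 450)
  n_motifs <- c(8L, 8L, 10L, 10L, 12L, 14L)
  groups <- lapply(seq_along(stages), function(i) {
    list(label = stages[i], n = n_per_stage,
         length_median = medians[i], length_log_sd = 0.35,
         sites_mean = medians[i] / 60,
         panel = panel_spec(sprintf("st%dTF", i), n_motifs[i],
                            I_range = c(7, 10)))
  })
  cohort_spec(groups = groups, seed = seed)
}

#' Generate a synthetic enhancer cohort
#'
#' Realises a [cohort_spec]: per group, builds the motif panel with
#' [generate_pwm] (training alignments included), draws enhancer lengths
#' from the group's log-normal distribution and planted-site counts from
#' its Poisson distribution (capped so sites always pack), and generates
#' each enhancer with [generate_enhancer]. Fully reproducible from the
#' spec's seed. Optionally writes every file the pipeline consumes.
#'
#' @param spec A [cohort_spec].
#' @param dir Optional output directory; when given, writes
#'   `enhancers.fasta`, `groups.tsv`, `truth.tsv`, `config.json`, and a
#'   `motifs/<group>/` tree of matrix + training-alignment files readable
#'   by [read_motif_set].
#' @return List: `enhancers` (data frame `id`, `group`, `sequence`,
#'   `length_bp`), `truth` (planted-site table), `panels` (named list of
#'   PWM lists per group), `background`, `spec`, and `dir` when written.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  bg <- spec$background
  enh <- list(); truth <- list(); panels <- list()
  gseed <- spec$seed
  for (g in spec$groups) {
    pan <- lapply(seq_len(nrow(g$panel)), function(i) {
      generate_pwm(g$panel$width[i], g$panel$target_I[i], bg,
                   seed = gseed * 1000L + i %% 1000L,
                   name = g$panel$name[i])
    })
    names(pan) <- g$panel$name
    panels[[g$label]] <- pan
    mean_w <- mean(g$panel$width)
    draws <- with_seed(gseed * 7L + 3L, {
      lens <- pmax(50L, round(stats::rlnorm(g$n, log(g$length_median),
                                            g$length_log_sd)))
      ns <- stats::rpois(g$n, g$sites_mean)
      list(lens = lens, ns = ns)
    })
    for (i in seq_len(g$n)) {
      len <- draws$lens[i]
      cap <- floor(0.6 * len / mean_w)  # keep site packing feasible
      n_sites <- min(draws$ns[i], cap)
      e <- generate_enhancer(len, pan, n_sites, bg,
                             seed = gseed * 100000L + gseed + i * 37L + nchar(g$label),
                             id = sprintf("%s_enh%03d", g$label, i),
                             group = g$label)
      enh[[length(enh) + 1L]] <- e$record
      truth[[length(truth) + 1L]] <- e$truth
    }
    gseed <- gseed + 101L
  }
  out <- list(enhancers = do.call(rbind, enh),
              truth = do.call(rbind, truth),
              panels = panels, background = bg, spec = spec)
  if (!is.null(dir)) {
    write_cohort(out, dir)
    out$dir <- dir
  }
  out
}
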