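write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Read an enhancer cohort from FASTA plus a group table
#'
#' Sequences come from a FASTA file; group labels from a two-column TSV
#' (`id`, `group`; a header row is optional). Sequences are uppercased
#' (soft-masking removed). Every FASTA id must have a group label; ids
#' missing one are rejected with the full list of offenders, as are
#' duplicate ids. Genomic coordinates can optionally be attached from a BED
#' file (0-based half-open) whose `name` column matches the FASTA ids.
#'
#' @param fasta_path FASTA of enhancer sequences.
#' @param groups_path Two-column TSV mapping id to group label.
#' @param bed_path Optional BED file (chrom, start, end, name).
#' @return Data frame: `id`, `group`, `sequence`, `length_bp`, and
#'   `chrom`/`start`/`end` when a BED is supplied.
#' @export
read_enhancers <- function(fasta_path, groups_path, bed_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate enhancer ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  gtab <- utils::read.delim(groups_path, header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("id", "group"))
  if (nrow(gtab) > 0 && identical(tolower(unlist(gtab[1, ])), c("id", "group"))) {
    gtab <- gtab[-1, , drop = FALSE]
  }
  if (nrow(gtab) == 0L) stop("empty group table: ", groups_path)
  if (anyDuplicated(gtab$id)) {
    stop("duplicate ids in group table: ",
         paste(unique(gtab$id[duplicated(gtab$id)]), collapse = ", "))
  }
  missing <- setdiff(ids, gtab$id)
  if (length(missing)) {
    stop("enhancer id(s) missing a group label: ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(id = ids,
                    group = gtab$group[match(ids, gtab$id)],
                    sequence = toupper(as.character(seqs)),
                    length_bp = Biostrings::width(seqs))
  if (any(out$group == "" | is.na(out$group))) {
    stop("empty group label for: ",
         paste(out$id[out$group == "" | is.na(out$group)], collapse = ", "))
  }
  if (!is.null(bed_path)) {
    bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
    names(bed)[1:4] <- c("chrom", "start", "end", "name")
    idx <- match(out$id, bed$name)
    out$chrom <- bed$chrom[idx]
    out$start <- bed$start[idx]
    out$end <- bed$end[idx]
  }
  rownames(out) <- NULL
  out
}

parse_matrix_lines <- function(lines, path) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  num <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*[|:]?", "", l)  # optional leading base label
    l <- gsub("\\[|\\]", " ", l)              # JASPAR brackets
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("unparseable matrix line in ", path, ": ", l)
    v
  })
  if (length(num) != 4L) stop("expected 4 matrix rows (A, C, G, T) in ", path,
                              ", got ", length(num))
  L <- unique(lengths(num))
  if (length(L) != 1L) stop("ragged matrix rows in ", path)
  mat <- do.call(rbind, num)
  rownames(mat) <- DNA_BASES
  mat
}

#' Read a PWM count matrix file
#'
#' Supports a plain whitespace-delimited dialect (4 rows in A, C, G, T
#' order, optionally labelled `A | ...`) and a JASPAR-style variant (a `>`
#' header line followed by `A [ ... ]` rows). A training alignment is
#' attached from `<stem>.sites.fasta` next to the matrix file when present.
#'
#' @param path Matrix file.
#' @param background A [background_model].
#' @param pseudocount_total Passed to [build_pwm].
#' @param name TF identifier; defaults to the JASPAR header name or the
#'   file stem.
#' @return A [build_pwm] object.
#' @export
read_pwm_file <- function(path, background, pseudocount_total = 0.01,
                          name = NULL) {
  lines <- readLines(path, warn = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  header <- grep("^>", lines, value = TRUE)
  if (is.null(name)) {
    if (length(header)) {
      toks <- strsplit(sub("^>\\s*", "", header[1]), "\\s+")[[1]]
      name <- if (length(toks) >= 2L) toks[2] else toks[1]
    } else {
      name <- stem
    }
  }
  mat <- parse_matrix_lines(grep("^>", lines, invert = TRUE, value = TRUE), path)
  train_path <- file.path(dirname(path), paste0(stem, ".sites.fasta"))
  training <- NULL
  if (file.exists(train_path)) {
    ts <- Biostrings::readDNAStringSet(train_path)
    training <- toupper(as.character(ts))
  }
  build_pwm(mat, background, pseudocount_total, name = name,
            training = training)
}

#' Write a PWM matrix (and its training alignment) to files
#'
#' @param pwm A [build_pwm] object.
#' @param path Output matrix file; the training alignment, if present, goes
#'   to `<stem>.sites.fasta` alongside.
#' @return `path`, invisibly.
#' @export
write_pwm_file <- function(pwm, path) {
  lines <- vapply(1:4, function(b) {
    paste(DNA_BASES[b], "|", paste(format(pwm$counts[b, ], trim = TRUE),
                                   collapse = " "))
  }, character(1))
  writeLines(lines, path)
  if (!is.null(pwm$training)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    fa <- file.path(dirname(path), paste0(stem, ".sites.fasta"))
    writeLines(paste0(">", pwm$name, "_site", seq_along(pwm$training), "\n",
                      pwm$training), fa)
  }
  invisible(path)
}

# TF identity of a motif file: stem up to an optional "__variant" suffix
tf_name_of <- function(path) sub("__.*$", "", sub("\\.[^.]*$", "", basename(path)))

#' Read a directory of motif files as one panel
#'
#' Reads every `.pwm`/`.jaspar`/`.txt` matrix in a directory. When several
#' files describe the same TF (file stems `tf__variant.pwm`), the matrix
#' with the largest training alignment is selected; an `override` map
#' (TF name to file name) pins a specific file instead, and every choice is
#' reported in the `selection` attribute.
#'
#' @param motif_dir Directory of matrix files (training alignments as
#'   `<stem>.sites.fasta` alongside).
#' @param background A [background_model].
#' @param pseudocount_total Passed to [build_pwm].
#' @param override Named character vector mapping TF name to the file name
#'   that must be used for it.
#' @return Named list of [build_pwm] objects (one per TF), with a
#'   `selection` attribute recording file, training size, and whether an
#'   override applied.
#' @export
read_motif_set <- function(motif_dir, background, pseudocount_total = 0.01,
                           override = NULL) {
  files <- list.files(motif_dir, pattern = "\\.(pwm|jaspar|txt)$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no motif files found in ", motif_dir)
  pwms <- lapply(files, function(f) {
    read_pwm_file(f, background, pseudocount_total, name = tf_name_of(f))
  })
  tf <- vapply(files, tf_name_of, character(1))
  ntrain <- vapply(pwms, function(p) {
    if (is.null(p$training)) 0L else length(p$training)
  }, integer(1))
  sel <- list(); out <- list()
  for (name in unique(tf)) {
    idx <- which(tf == name)
    if (!is.null(override) && name %in% names(override)) {
      pick <- idx[basename(files[idx]) == override[[name]]]
      if (length(pick) != 1L) {
        stop("override for '", name, "' names no file in ", motif_dir)
      }
      why <- "override"
    } else {
      pick <- idx[which.max(ntrain[idx])]
      why <- if (length(idx) > 1L) "largest_training_alignment" else "only_file"
    }
    out[[name]] <- pwms[[pick]]
    sel[[name]] <- data.frame(tf_name = name, file = basename(files[pick]),
                              n_training = ntrain[pick], rule = why,
                              n_candidates = length(idx))
  }
  attr(out, "selection") <- do.call(rbind, sel)
  out
}

#' Write a hit table as BED6
#'
#' Enhancer-relative coordinates: `chrom` is the enhancer id, `start` the
#' 0-based offset, `score` is `round(100 * bits)` clamped to 0-1000.
#'
#' @param hits Hit table from [find_hits].
#' @param widths Named vector of motif widths (TF name -> width).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, widths, path) {
  bed <- data.frame(chrom = hits$enhancer_id,
                    start = hits$offset,
                    end = hits$offset + widths[hits$tf_name],
                    name = hits$tf_name,
                    score = pmax(0L, pmin(1000L, round(100 * hits$score))),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", cohort$enhancers$id, "\n", cohort$enhancers$sequence),
             file.path(dir, "enhancers.fasta"))
  utils::write.table(cohort$enhancers[, c("id", "group")],
                     file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  for (grp in names(cohort$panels)) {
    mdir <- file.path(dir, "motifs", grp)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (pwm in cohort$panels[[grp]]) {
      write_pwm_file(pwm, file.path(mdir, paste0(pwm$name, ".pwm")))
    }
  }
  jsonlite::write_json(
    list(q = as.list(cohort$background$q), N = cohort$background$N,
         seed = cohort$spec$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

run_manifest <- function(params, counts) {
  list(package = "enhancerarch",
       version = as.character(utils::packageVersion("enhancerarch")),
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = params, counts = counts)
}
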