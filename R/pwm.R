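DNA_BASES <- c("A", "C", "G", "T")

# integer encoding A=1 C=2 G=3 T=4; anything else NA
.base_lookup <- local({
  x <- rep(NA_integer_, 128L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
})

encode_dna <- function(seq) {
  codes <- utf8ToInt(toupper(seq))
  codes[codes > 128L | codes < 1L] <- 1L  # map out-of-range to an NA slot safely
  .base_lookup[codes]
}

decode_dna <- function(ints) paste(DNA_BASES[ints], collapse = "")

# reverse complement in integer encoding (NA preserved)
revcomp_ints <- function(ints) rev(5L - ints)

revcomp_dna <- function(seq) decode_dna(revcomp_ints(encode_dna(seq)))

#' Background base-composition model
#'
#' Base frequencies of the (intergenic) genomic background together with the
#' accessible genome size. Used for pseudocounting, log-odds scoring, the
#' score-distribution dynamic program, and information content.
#'
#' @param q Numeric vector of 4 base frequencies in A, C, G, T order (named
#'   or unnamed); must be positive and sum to 1 within 1e-9. Default is an
#'   AT-rich, complement-symmetric composition typical of Drosophila
#'   intergenic sequence.
#' @param N Accessible genome size in bp or a name from
#'   [accessible_genome_sizes].
#' @return An object of class `background_model` with elements `q` (named
#'   frequencies) and `N`.
#' @export
background_model <- function(q = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                             N = "dnase_conservative") {
  stopifnot(length(q) == 4L, all(is.finite(q)))
  if (any(q <= 0)) stop("background frequencies must all be positive")
  if (abs(sum(q) - 1) > 1e-9) stop("background frequencies must sum to 1")
  q <- as.numeric(q)
  names(q) <- DNA_BASES
  structure(list(q = q, N = resolve_genome_size(N)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background model: q =",
      paste(sprintf("%s=%.3f", DNA_BASES, x$q), collapse = " "),
      sprintf("| N = %.1f Mb\n", x$N / 1e6))
  invisible(x)
}

#' Background composition from intergenic sequence
#'
#' Counts A/C/G/T over all sequences in a FASTA file (ambiguity codes are
#' ignored) and returns the corresponding [background_model].
#'
#' @param fasta_path Path to a FASTA file of background/intergenic sequence.
#' @param N Accessible genome size (bp or name).
#' @return A `background_model`.
#' @export
background_from_fasta <- function(fasta_path, N = "dnase_conservative") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no sequences in ", fasta_path)
  counts <- colSums(Biostrings::alphabetFrequency(seqs)[, DNA_BASES, drop = FALSE])
  if (sum(counts) == 0) stop("no unambiguous bases in ", fasta_path)
  background_model(q = counts / sum(counts), N = N)
}

alignment_to_counts <- function(seqs) {
  if (length(seqs) == 0L) stop("empty training alignment")
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must all have equal length")
  if (any(grepl("[^ACGT]", seqs))) {
    stop("ambiguity codes in training alignment are not supported")
  }
  mat <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  enc <- vapply(seqs, encode_dna, integer(L))
  if (L == 1L) enc <- matrix(enc, nrow = 1L)
  for (i in seq_len(L)) {
    tab <- tabulate(enc[i, ], nbins = 4L)
    mat[, i] <- tab
  }
  mat
}

#' Build a position weight matrix
#'
#' Constructs a PWM from a 4 x L count (or frequency-mass) matrix, or from a
#' set of aligned binding-site sequences. Pseudocounts totalling
#' `pseudocount_total` are added to each column in proportion to the
#' background frequency of the corresponding base:
#' \deqn{p_i(b) = \frac{c_i(b) + t\,q(b)}{C_i + t}}
#' where `c_i(b)` is the observed count mass, `C_i` the column total and `t`
#' the pseudocount total (default 0.01).
#'
#' @param x Either a numeric 4 x L matrix (rows in A, C, G, T order) of
#'   non-negative counts, or a character vector of equal-length aligned
#'   sequences over A/C/G/T.
#' @param background A [background_model].
#' @param pseudocount_total Total pseudocount mass added per column.
#' @param name TF identifier.
#' @param training Optional character vector of training sequences
#'   (binding sites, possibly longer than the motif) used later by
#'   [calibrate_cutoff]. When `x` is an alignment it doubles as the training
#'   set unless `training` is supplied.
#' @return An object of class `pwm` with elements `name`, `width`, `freqs`
#'   (pseudocounted 4 x L frequency matrix), `counts`, `training`,
#'   `pseudocount_total`.
#' @export
build_pwm <- function(x, background, pseudocount_total = 0.01,
                      name = "motif", training = NULL) {
  stopifnot(inherits(background, "background_model"),
            pseudocount_total >= 0)
  if (is.character(x)) {
    counts <- alignment_to_counts(x)
    if (is.null(training)) training <- toupper(x)
  } else {
    counts <- as.matrix(x)
    if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A, C, G, T)")
    if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be non-negative")
    rownames(counts) <- DNA_BASES
  }
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every PWM column must have positive total count")
  q <- background$q
  freqs <- sweep(counts + pseudocount_total * q, 2L,
                 totals + pseudocount_total, "/")
  if (any(freqs <= 0)) stop("zero frequency after pseudocounting; use pseudocount_total > 0")
  stopifnot(all(abs(colSums(freqs) - 1) < 1e-9))
  structure(list(name = name, width = ncol(freqs), freqs = freqs,
                 counts = counts, training = training,
                 pseudocount_total = pseudocount_total),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, %s training sequences\n",
              x$name, x$width,
              if (is.null(x$training)) "no" else length(x$training)))
  print(round(x$freqs, 3))
  invisible(x)
}

consensus_string <- function(pwm) {
  decode_dna(apply(pwm$freqs, 2L, which.max))
}
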