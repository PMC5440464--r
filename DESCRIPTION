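Package: enhancerarch
Title: Enhancer Architecture and Regulatory Task Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of how the complexity of an enhancer's regulatory task
    shapes its architecture (length, transcription factor binding site number,
    and average binding specificity). Implements a binomial model of motif
    cluster distinguishability from genomic background, position weight matrix
    scanning with exact score-distribution ln(p-value) thresholds calibrated on
    the motif's own training alignment, Kullback-Leibler information content
    and average motif hit probability statistics, nonparametric group
    comparisons with Bonferroni correction, and a synthetic enhancer cohort
    generator with planted binding sites for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
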