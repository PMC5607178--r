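Package: txguide
Title: Transcriptome-Guided Read Assignment, Assembly and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transcriptome-guided assembly toolkit for non-model species.
    Simulates RNA-seq reads of known gene origin under controlled sequence
    divergence, quality-filters them, assigns each read to a gene by best
    local-alignment hit against one or more reference transcriptomes (with
    explicit handling of paralog and cross-species score ties), assembles the
    assigned reads per gene with a greedy overlap-consensus assembler, and
    scores the result with recovery rate, specificity rate, a five-way gene
    typology, and per-gene completeness and contiguity against the longest
    reference transcript. Includes a seed-and-extend local aligner with an
    exact Smith-Waterman cross-check, tidy tabular outputs, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    BiocGenerics,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
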