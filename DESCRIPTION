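Package: plasmidlead
Title: Leading-Region Orientation and Anti-Defence Gene Enrichment in
    Conjugative Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orients conjugative-element contigs into leading and lagging
    regions relative to the origin of transfer (oriT), using relaxase/TraM
    homology hits and a seeded short-word nucleotide aligner for oriT
    detection. Quantifies positional and gene-family enrichment of
    anti-defence functions (anti-CRISPR, anti-restriction, SOS inhibitors)
    with one-sided Fisher exact tests and Benjamini-Hochberg FDR control,
    delineates anti-defence islands bounded by the oriT and umu-like
    operons, and detects Frpo/ssi single-stranded-DNA promoter candidates
    by homology, sigma-70 consensus-element scanning and base-pair
    maximization hairpin evidence. Ships a synthetic contig simulator with
    planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    IRanges,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
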