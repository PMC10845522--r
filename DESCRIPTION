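Package: vitiscan
Title: Copy-Number, Repeatome and Satellite-DNA Profiling for Grapevine Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth copy-number profiling and WSSD-style duplication/deletion
    calling in fixed-unmasked-size windows, in-silico digital CGH log2-ratio
    detection of copy-number-variant regions and their cross-variety
    intersection, chi-square testing of variant distribution across
    chromosomes, a read-based repeatome profiler (shared k-mer clustering,
    repeat-family classification, genome-proportion landscapes), and
    satellite-DNA characterization with in-silico chromosomal mapping.
    Includes a synthetic-genome simulator with recorded ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
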