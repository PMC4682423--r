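Package: subseqnet
Title: Reliable Gene Interaction Networks from Conserved Subsequential
    Patterns in Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene interaction networks (GINs) from multiple
    time-course gene expression datasets. Expression profiles are
    discretized into a seven-level alphabet relative to a per-gene scale,
    closed subsequential patterns are mined under a similarity algebra on
    adjacent-level pair-items (capturing positive, negative and
    time-lagged co-expression over sub-windows of time points),
    per-dataset networks built from pattern co-membership are integrated
    with per-polarity edge weights, and edges conserved across almost all
    datasets are retained as a reliable GIN. Includes a Pearson
    correlation baseline, precision/recall evaluation against reference
    edge sets, a planted-module synthetic data generator, and an
    exhaustive brute-force mining oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    tibble,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
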