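Package: aptaprofile
Title: Aptamer Library Sequencing Profiles of Complex Protein Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of branched-selection aptamer sequencing experiments in
    which the per-sample read distribution of an enriched RNA aptamer library
    serves as a proxy for the global protein composition of a biofluid.
    Provides demultiplexing of barcoded reads into count matrices, joining of
    near-identical sequences into ancestor families by Damerau-Levenshtein
    distance, compositional (percent-of-total, mean-scaled) normalization,
    per-sequence ordinary least squares contrasts with Benjamini-Hochberg
    false-discovery control and effect-size thresholds, validation of
    descriptive-sequence panels on an independent cohort via principal
    component scores and Wilcoxon rank-sum tests, k-mer motif family
    construction, pull-down proteomics relative-abundance profiles, and a
    synthetic-cohort generator with planted condition effects for benchmarking
    every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
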