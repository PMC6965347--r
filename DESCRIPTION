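Package: tpattern
Title: T-Pattern Detection and Analysis for Time-Stamped Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and analysis of T-patterns: recurring hierarchical
    temporal patterns of categorical events on a discrete time axis.
    Pairs of event series are related by critical intervals found with an
    exact binomial tail test against a null of independent random
    placement, and significant pairs are assembled bottom-up into binary
    trees, with a completeness competition removing redundant detections.
    Includes T-burst detection within single series, a [1,1]-restricted
    mode for recurrent substring discovery in text and biological
    sequences, Monte Carlo validation against shuffling and rotation
    surrogates, synthetic data generators with planted ground truth, and
    post-detection selection and summary tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
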