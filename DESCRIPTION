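Package: minicircle
Title: Sequence Register Mapping, Deformability Profiling and
    Step-Geometry Analysis for Circular DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating protein-bound DNA segments on small circular
    DNA (minicircles) and characterising their mechanics. Converts sequences
    to purine/pyrimidine (R/Y) profiles and scans circular references on both
    strands with a mismatch/unresolved tolerance budget, with exact analytic
    random-match probabilities; profiles sequence-dependent base-pair-step
    deformability from tetramer-context lookup tables with periodic
    sliding-window averaging and percentile ranking; classifies base-pair
    steps as A-, B- or TA-form from phosphorus-based descriptors, rebuilds
    three-dimensional base-pair frames from rigid-body step parameters and
    determines superhelical handedness of the rebuilt axis; and scores
    circular sequences against gyrase-motif position weight matrices with
    region splitting. Includes seeded synthetic-data generators so every
    analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
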