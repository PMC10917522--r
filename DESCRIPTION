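Package: brewtrack
Title: Temporal Proteomics and Genome Profiling of Serially Repitched Brewing Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for label-free shotgun proteomics
    time courses and companion genome profiling, motivated by serial
    repitching of brewing yeast. Quantifies proteins from peptide evidence
    (spectral-count ppm, iBAQ, summed intensity with median-ratio
    normalization), applies replicate-detection filters, tests all
    time-point pairs for differential expression with Benjamini-Hochberg
    control, clusters temporal profiles with average linkage and node-depth
    cluster extraction, runs hypergeometric set enrichment, computes
    complex/compartment co-regulation correlation profiles, scores metabolic
    pathway perturbation (DRPS/DPPS) with leave-enzymes-out re-ranking, and
    profiles copy number and loss of heterozygosity from windowed read
    depth and variant allele counts. A synthetic-data generator with known
    ground truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
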