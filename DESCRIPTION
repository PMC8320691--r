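Package: reactomics
Title: Paired Mass Distance Analysis of Untargeted High-Resolution
    Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-level analysis of untargeted high-resolution mass
    spectrometry (HRMS) data through paired mass distances (PMDs), without
    annotating individual compounds. Computes reaction PMDs from
    substrate/product sets, mines reaction and compound databases into PMD
    frequency databases, finds and classifies static versus dynamic PMD peak
    pairs in experimental peak tables, performs relative quantitative PMD
    analysis for biomarker-reaction discovery, screens halogenated peaks via
    isotopologue spacing, and builds PMD networks for annotation and
    endogenous/exogenous source appointment. Includes seeded synthetic-data
    generators with known ground truth and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
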