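Package: secretomics
Title: Compartment-Resolved Label-Free Proteomics of Bacterial Protein
    Secretion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for compartment-resolved label-free
    quantitative (LFQ) proteomics of secreting bacteria. Implements
    replicate- and localization-based protein qualification, presence
    (ON/OFF) calling under intensity-dependent missingness, S0-moderated
    two-sample statistics with permutation-based false-discovery-rate
    control (with a Benjamini-Hochberg alternative), functional-category
    and regulon aggregation with treemap export, the Sec-pathway
    secretion-proportion statistic, and promoter-activity (TAU)
    computation from live-cell-array plate-reader time series. Ships a
    synthetic-data generator with known ground truth so every stage can
    be validated without raw mass-spectrometry data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
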