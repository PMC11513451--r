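Package: proteocut
Title: Time-Resolved Analysis of Targeted Proteolysis from Peptide
    Intensity Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for time-resolved targeted proteolysis
    (degradomics) experiments. Maps LC-MS peptide products onto a substrate
    protein, filters them against protease-free controls with a homogeneity
    of regression slope test, computes the relative frequency of cuts at
    each P1 residue over time, profiles protease specificity around the
    scissile bond (P5-P5'), annotates cleavage sites with secondary
    structure, B-factors, solvent accessibility and sequence conservation,
    and orders cleavage events into a sequential substrate-unfolding model.
    Includes a stochastic simulator of accessibility-gated digestion of a
    folded substrate ensemble for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
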