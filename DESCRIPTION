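Package: cyp21act
Title: Structure-Based Residual-Activity Prediction for CYP21A2 Stability Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the residual 21-hydroxylase activity of CYP21A2 missense
    variants from protein-stability changes (delta-delta-G, kcal/mol). Parses
    protein-level variant labels, classifies variants by structural context
    (heme/ligand contact, POR-interface membership, annotated motifs), ingests
    and aggregates FoldX-style per-replica stability estimates, fits a
    log-linear calibration of in vitro residual activity on delta-delta-G with
    permutation-based significance, calls pathogenicity and clinical severity
    bands, and scores additivity and synergy of two variants in cis. Includes
    synthetic-data generators (calibration pairs, replica sets, double-variant
    scenario sets, and toy PDB fixtures with controlled heme geometry) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
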