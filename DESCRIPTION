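Package: paleopept
Title: Authentication and Collagen Characterization for Paleoproteomic Peptide Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating ancient proteins in shotgun paleoproteomic
    experiments and characterizing collagen type I alpha chains. Reads MaxQuant
    evidence-style peptide tables, estimates intensity-weighted chemical
    modification levels (deamidation of Asn/Gln, oxidative modifications) with
    bootstrap confidence intervals separately for endogenous and contaminant
    peptide populations, profiles peptide taxonomy with a lowest-common-ancestor
    algorithm over a rooted taxonomy, classifies proteins by marker-peptide rules,
    and maps observed peptides onto collagen alpha-chain references with
    substitution and indel calling, coverage computation and Gly-Xaa-Yaa triplet
    validation. Includes a fully labeled synthetic-data generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
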