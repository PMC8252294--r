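Package: trichomeRF
Title: Linking Trichome-Borne Metabolites to Insect Resistance with
    Permutation-Null Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for identifying trichome-borne specialised metabolites
    (acylsugars and volatiles) that discriminate insect-resistant from
    insect-susceptible tomato accessions. Provides bioassay phenotyping via
    binomial GLMs on whitefly clip-cage survival and Cox proportional-hazards
    plus Kaplan-Meier models on thrips time-to-event records; metabolite
    annotation utilities (acylsugar S/G-k:N nomenclature from CHO molecular
    formulas via double-bond-equivalent stoichiometry, adduct m/z, Kovats
    retention indices, normalisation and feature-table construction); the core
    repeated cross-validated random-forest feature-importance selection with
    label-permutation null distributions and per-metabolite empirical
    p-values; association reporting (relative survival, trichome-density
    regressions, complete-linkage clustering); and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
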