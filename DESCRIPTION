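Package: eoblend
Title: Mixture-Design Optimization of Essential-Oil Blends Against
    Carbohydrate-Digesting Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for formulating and analysing ternary essential-oil blends
    that inhibit pancreatic alpha-amylase and intestinal alpha-glucosidase.
    Generates augmented simplex-centroid mixture designs, estimates IC50 from
    dose-inhibition curves on the log-concentration scale, fits the Scheffe
    special-cubic polynomial by intercept-free least squares with a full
    lack-of-fit analysis of variance, locates optimal blends on the simplex via
    dense grid search with desirability scoring, and derives conceptual-DFT
    global reactivity descriptors (hardness, electronegativity, maximal
    electron transfer) from frontier-orbital energies, plus Kovats retention
    indices from an n-alkane ladder. A synthetic-data module simulates the full
    study design for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
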