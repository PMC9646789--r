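Package: chousyn
Title: Median-Effect Dose-Effect Modelling and Drug-Combination Synergy
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies drug-drug interaction from enzyme-inhibition assays
    with the mass-action median-effect model of Chou and Talalay. Converts
    kinetic absorbance-time traces into reaction velocities and percent
    inhibition, fits the linearized median-effect equation (Dm, m, r) and a
    constrained four-parameter logistic for IC50, and assesses fixed-ratio
    drug combinations through the combination index, dose-reduction index,
    fa-CI profiles and normalized isobolograms. Includes a virtual-screening
    score aggregator that ranks plants by their docking-hit activity, a
    synthetic-data generator for kinetic traces with median-effect scaled
    velocities, and a literature benchmark of hDHODH inhibitor dose-effect
    tables.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
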