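Package: switchflux
Title: Enzyme-Constrained Metabolic Models of the Streptomyces Metabolic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of the phosphate-depletion metabolic
    switch in antibiotic-producing Streptomyces. Provides a compact
    genome-scale modelling toolkit (flux balance and flux variability
    analysis on a built-in bounded-variable simplex solver, SBML and tabular
    model input/output), thermodynamics-guided curation of reaction
    directionality arbitrated by growth/knockout phenotype tests,
    GECKO-style enzyme-constrained model construction with proteome and
    exchange-rate integration, random vertex sampling of the flux polytope
    with CO2-normalized pathway activity scores and metabolite source/sink
    budgets, cultivation time-series rate estimation (growth rates,
    depletion times, specific uptake/secretion rates, cross-strain
    production comparisons), regulon-based time-point alignment and
    proteome ordination, and a seeded synthetic-data generator emulating
    batch fermentations of an M145-like producer strain and its
    cluster-deletion mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
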