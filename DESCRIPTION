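Package: prostimm
Title: Tumor-Immune Dynamics and Treatment Synergy Modelling for Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-compartment (prostate and lymphoid) ordinary differential
    equation model of prostate tumor-immune dynamics under androgen-deprivation
    therapy (castration), tumor-cell vaccination, IL-2 neutralization and
    regulatory T cell depletion. Provides forward simulation of all 16
    treatment regimens, generation of mouse-experiment-like longitudinal
    datasets, calibration of the 25 model rate constants with a real-coded
    genetic algorithm preceded by grid-based selection of its own
    hyperparameters, bootstrap coefficient-of-variation identifiability
    analysis, leave-one-condition-out and leave-one-data-box-out
    cross-validation with replicate-fit confidence bands, local parameter
    sensitivity analysis, and Bliss-independence combination-index synergy
    ranking of combined regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
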