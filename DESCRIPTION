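Package: ergofit
Title: Endurance-Phenotype Modelling from Laboratory Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tidy tools for characterizing the endurance phenotype from
    laboratory time-series recordings. Cleans, interpolates and
    ensemble-averages breath-by-breath gas-exchange data and fits the
    phase-II mono-exponential model of pulmonary oxygen-uptake on-kinetics;
    extracts peak oxygen uptake, peak power output and the gas-exchange
    threshold (simplified v-slope breakpoint) from incremental ramp tests;
    computes gross efficiency from steady-state gas exchange; segments
    5-min all-out critical-torque tests into contraction cycles and derives
    critical torque and impulse-prime; fits exponential-decay critical-ratio
    models to paired torque and near-infrared-spectroscopy muscle-oxygenation
    signals; and analyses flow-mediated dilation recordings (baseline and
    peak diameter, shear rate and its area under the curve). A seeded
    synthetic-signal generator produces all four signal families with known
    ground truth so every analysis stage is verifiable by parameter recovery.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
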