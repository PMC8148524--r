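Package: lipidox
Title: Kinetic Shelf-Life Modelling of Lipid Oxidation (TBARS) in Raw Meat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predictive modelling of secondary lipid oxidation in raw ground
    meat enriched with plant extracts, measured as thiobarbituric acid
    reactive substances (TBARS). Fits first-order formation kinetics per
    storage temperature, models the temperature dependence of the rate
    constant by the Arrhenius and log-logistic equations, builds integrated
    shelf-life prediction models with external validation at a held-out
    temperature, compares treatments by dummy-coded multiple linear
    regression, and provides a multilayer-perceptron regression comparator.
    Includes a synthetic-data generator emulating the multi-temperature
    storage design so every stage is testable without laboratory data, and
    packaged reference tables of extract antioxidant assays and published
    rate constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
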