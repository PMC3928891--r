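Package: PoUcast
Title: Prevalence of Undernourishment Estimation and Scenario Projection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the prevalence and headcount of undernourishment in a
    population following the FAO dietary-energy-deficiency methodology: mean
    dietary energy supply is derived from commodity-level food balance sheets,
    inequality of access skews a lognormal consumption distribution via the
    Gini coefficient, and the minimum dietary energy requirement is computed
    from basal metabolic rate and physical activity levels over the age-sex
    structure of the population. Baselines can be projected forward under
    climate and population scenarios expressed as percentage changes in C3/C4
    crop productivity and trade relative to a defined baseline year. Includes
    a seeded synthetic-data generator for all inputs, a Monte Carlo validator
    for the closed-form prevalence estimator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'fbs.R'
    'demography.R'
    'distribution.R'
    'scenario.R'
    'synth.R'
    'validate.R'
    'cli.R'
    'show-methods.R'
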