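Package: phenoflight
Title: Degree-Day Phenology Models for Black Cutworm Flight and Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating insect phenology models from
    daily temperature series, pheromone-trap catches, and constant-temperature
    rearing data, developed around the black cutworm (Agrotis ipsilon) in
    Pacific Northwest grass seed and vegetable systems. Computes daily and
    accumulated growing degree days under simple-average, single-triangle,
    and single-sine methods; estimates lower developmental thresholds and
    thermal constants from development-rate regressions; fits three-parameter
    logistic flight curves to cumulative trap catch on a degree-day axis with
    variance-power heteroskedasticity; selects the degree-day start date
    (biofix) by grid search; validates by year-split cross-validation; and
    projects calendar windows of life stages forward from a biofix. Includes
    seeded synthetic-data generators so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
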