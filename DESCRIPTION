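Package: ghgediet
Title: Diet Optimization Minimizing Greenhouse Gas Emissions by Linear
    Programming
Version: 0.1.0
Authors@R:
    person("ghgediet", "developers", email = "ghgediet@example.org",
           role = c("aut", "cre"))
Description: Builds a per-food-group greenhouse-gas-emission (GHGE)
    coefficient database from literature life-cycle-assessment data
    points, processes food-consumption-survey diaries into sex-stratified
    population statistics, assembles nutritional (dietary reference
    intake and percent-of-energy), acceptability (observed-intake
    percentile) and healthy (food-group policy) linear constraints over
    55 food subcategory amounts, and solves the GHGE-minimizing linear
    program with an infeasibility diagnostic that maximizes a suspect
    nutrient over the remaining feasible set. Includes observed-versus-
    optimized diet reporting and a synthetic-data generator emulating a
    national 3-day-diary consumption survey so the whole pipeline is
    testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    boot,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
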