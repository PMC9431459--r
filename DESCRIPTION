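Package: crococompete
Title: Competition Modelling and Nitrogen Budgets for Unicellular Diazotrophs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the competitiveness of the unicellular diazotrophic
    cyanobacterium Crocosphaera for combined nitrogen. Provides sum-of-Monod
    uptake growth kinetics fitted to bottle-incubation time series, a
    nutrient-phytoplankton-zooplankton competition simulator with
    kill-the-winner grazing and an optional diazotrophy growth-rate floor,
    flow-cytometry based cellular carbon and nitrogen biomass estimation
    (bead size calibration, volumetric and Strathmann carbon models, C:N
    conversion), acetylene-reduction based nitrogen-fixation budgets, a
    multistart least-squares parameter-fitting harness, and a seeded
    synthetic-experiment generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
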