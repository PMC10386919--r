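Package: boostercost
Title: Micro-Costing and Scale-Up Modelling of Phone-Delivered Booster
    Counselling Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingredient-based micro-costing pipeline for brief
    counselling interventions whose booster sessions are delivered by
    live phone calls, SMS dialogues, or interactive voice response
    (IVR). Validates line-item cost ledgers stratified by time period
    (start-up vs implementation), resource class (capital vs
    recurring), cost level (intervention, counselor, participant) and
    delivery arm; allocates shared costs from staff effort logs;
    aggregates per-arm and per-participant cost tables with percentage
    composition; re-prices the intervention under four replication
    scenarios (NGO/Ministry-of-Health operator crossed with
    stand-alone/integrated staffing, with stepwise counselor hiring);
    and sweeps enrolment size to produce economy-of-scale curves,
    crossover detection and large-n asymptotes. Ships the observed
    cost tables of a three-arm trial in southwestern Uganda as
    plain-text fixtures, plus a seeded synthetic-data generator for
    property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
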