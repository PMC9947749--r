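Package: pufftopo
Title: Puff Topography and Nicotine-Emission Analysis for Puff-Recording
    Electronic Nicotine Delivery Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing actual-use behaviour recorded by
    puff-recording electronic nicotine delivery systems (PR-ENDS):
    validated ingestion of per-puff event logs and baseline surveys,
    calibration-anchored per-puff nicotine-emission estimation, puff
    topography descriptive statistics and effect sizes (eta-squared,
    Cohen's d), per-user coefficient-of-variation variability,
    relative-day cohort time courses with adaptation metrics, and a
    seeded synthetic-cohort generator that emulates a two-month,
    ~200,000-puff observational study so every stage of the pipeline is
    testable without access to raw device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
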