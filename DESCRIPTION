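Package: nightlightr
Title: Mobility-Oriented Measurement of Outdoor Artificial Light at Night Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures people's exposure to outdoor artificial light at night
    (ALAN) from nighttime-light (NTL) satellite imagery and GPS activity-travel
    trajectories. Provides radiometric calibration of raw digital numbers
    (power-law and gain/bias models), cross-sensor linear calibration,
    resolution degradation, exact area-weighted buffer-zone zonal statistics,
    sunset/sunrise computation, time-weighted mobility-oriented and
    residence-based exposure estimators, a 40-setting contextual measurement
    matrix for studying the uncertain geographic context problem (UGCoP),
    paired and Welch t-test disparity batteries, adjusted binary logistic
    exposure-health models, and a fully seeded synthetic-data generator
    (two-community nightscapes, multi-sensor views, week-long 1-minute
    trajectories, cohorts and outcomes) so the entire pipeline runs without
    confidential GPS or licensed satellite data.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
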