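Package: arsearch
Title: Encounter-Conditional Analysis of Forager Movement Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-level analysis of encounter-annotated GPS foraging tracks,
    contrasting adaptive area-restricted search with non-conditional Levy
    flights. Reads GPX tracks and encounter annotations, converts fixes to
    polar step series (step size, heading, unit-scaled turning angle), fits
    lagged Bayesian Beta and log-normal regressions of movement on past prey
    encounters (with AR-1 and encounter-type robustness variants), compares
    candidate step-size distributions by WAIC, computes patch-conditional
    regressions, and simulates foragers (area-restricted search in a clustered
    prey field, or Levy flight) so the full pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    fitdistrplus,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
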