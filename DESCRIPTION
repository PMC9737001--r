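Package: hospitalflow
Title: Whole-Hospital Patient-Flow Simulation and Decongestion Scenario Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of patient flow through a large
    tertiary hospital (emergency department, acute medical unit, medical and
    surgical wards), with a synthetic hospital-parameter generator, hourly
    congestion detection from joint occupancy and queue-length criteria, a
    catalogue of 27 congestion-triggered decongestion scenarios (bed
    right-sizing, ED out-transfers, early discharges, elective postponement,
    ambulance diversion and combinations), replication-based experiments with
    common random numbers, and efficiency statistics expressed as congestion
    reduction per affected patient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
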