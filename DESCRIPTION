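Package: temrel
Title: Technical Error of Measurement and Observer Reliability for
    Repeated Anthropometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimators of the technical error of measurement (TEM) for
    repeated anthropometric measurements: intra-observer and
    inter-observer TEM, relative TEM (%TEM), coefficients of reliability,
    and combined (total) TEM pooling both error sources. Includes
    acceptability classification against published field standards,
    best/worst-case imprecision scenarios, and estimation of the fraction
    of a longitudinal change attributable to measurement error. Ships a
    seeded generator of observer-structured measurement data for
    validation and parameter-recovery studies, long-format CSV ingestion
    with validation and replicate averaging, and a reporting layer that
    renders reliability tables and a machine-readable JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
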