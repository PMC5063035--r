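Package: asthmaclaims
Title: Claims-Based Detection of Inappropriate Asthma Therapy Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacoepidemiology pipeline for longitudinal medication-claims
    data. Builds asthma cohorts from prescription- or dispensation-style event
    tables (entry at the third distinct-date respiratory-drug event within a
    cohort year, 12-month lookback exclusions, 12-month follow-up), classifies
    three inappropriate patterns of asthma therapy over follow-up (overuse of
    short-acting beta-agonists, long-acting beta-agonist use without inhaled
    corticosteroids, and unbalanced LABA/ICS use), compares cohorts with
    chi-squared and Mann-Whitney tests, and extrapolates cohort prevalences to
    national burden counts by direct standardisation. Ships a two-dialect
    synthetic claims generator with constructively planted eligibility and
    pattern assignments so the whole pipeline is testable without access to
    restricted databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
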