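Package: dietpaf
Title: Population Attributable Fractions for Dietary Cancer Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates population attributable fractions (PAFs) and excess
    cancer cases for categorical dietary exposures with continuous
    dose-response relative risks. Published relative risks reported per
    consumption increment are converted to per-unit log-risk slopes,
    individual-level consumption records are summarised into per-stratum
    exposure-category distributions relative to guideline reference levels,
    and Levin-type PAFs are combined with cancer-registry counts under a
    latency offset between exposure and diagnosis. Includes a seeded
    synthetic-data generator (zero-inflated log-normal consumption,
    risk-proportional case allocation) with an enumerated individual-level
    attributable-fraction oracle, so the whole pipeline is testable offline.
    Ships the published risk, prevalence, and burden tables for a Texas 2015
    colorectal-cancer diet analysis as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
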