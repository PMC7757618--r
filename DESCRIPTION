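Package: usibenefits
Title: Health and Economic Benefits of Universal Salt Iodization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the health and economic benefits of universal salt
    iodization (USI) at country, WHO-region and global level. Converts
    population median urinary iodine concentration (MUIC) into a modeled
    total goiter rate (TGR) through a log-log power regression, computes
    clinical iodine-deficiency-disorder (IDD) burdens under observed and
    counterfactual "doing nothing" scenarios, and translates newborn IDD
    cases into net-present-value lifetime productivity losses via an
    IQ-to-earnings chain with annual discounting. Includes a synthetic
    country-table and survey-point generator so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
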