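Package: dxinterval
Title: Cancer Diagnostic Intervals and Diagnostic-Pathway Equity from
    Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring inequities in the time to cancer diagnosis
    from linked administrative health data. Implements an empirical
    diagnostic-interval algorithm (frequency-ratio selection of cancer-related
    encounter types, control-chart derivation of per-type lookback windows,
    first-contact resolution with a 365-day referral lookback), hierarchical
    classification of severe psychiatric illness exposure, diagnostic-pathway
    and symptom-status classification, and stratified quantile-regression
    contrasts of interval length at the 50th and 90th percentiles with
    bootstrap confidence intervals. Includes a seeded generator of synthetic
    linked claims tables with known ground truth so the full analytic chain is
    testable without access to real health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    quantreg,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
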