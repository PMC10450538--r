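Package: surgecase
Title: Case-Only Analysis of Effect Modification by Surges in a Daily Exposure Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates multiplicative interaction (effect modification) between
    surge days in a daily environmental exposure series and individual
    characteristics of death records, using the case-only design. Surge days
    are detected by percentile thresholding of the previous-day ratio of a
    (optionally denoised) daily count series; death records are filtered by
    ICD-10 cause ranges, recoded, and merged with the exposure calendar at
    configurable lags; interactions are estimated as closed-form case-only
    odds ratios (binary characteristics) and multinomial relative risk ratios
    (multi-level characteristics), each cross-checked against maximum
    likelihood fits and a saturated Poisson log-linear oracle. A synthetic
    data generator draws death records from the underlying Poisson
    interaction model with known ground truth, so the whole pipeline is
    testable by parameter recovery without access to restricted mortality or
    commercial social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
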