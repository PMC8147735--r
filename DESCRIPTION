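Package: concindex
Title: Survey-Weighted Concentration Indices for Health Inequality
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures socioeconomic inequality in health indicators from
    household survey microdata using the concentration index.  Provides
    weighted fractional ranks with tied-block handling, the standard
    (covariance) and convenient-regression estimators with conventional
    weighted-least-squares standard errors, the Wagstaff normalization
    for bounded and binary indicators, concentration curves, and a full
    analysis pipeline for multi-country surveys: within-country wealth
    ranking, cross-country wealth scaling by per-capita GDP at
    purchasing-power parity, population-share weight rescaling,
    descriptive tables, and country-by-indicator inequality matrices.
    Includes a synthetic multi-country survey generator with analytic
    ground-truth indices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
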