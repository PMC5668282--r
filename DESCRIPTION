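Package: hlseason
Title: Seasonality of Hodgkin Lymphoma Incidence and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing seasonal patterns in cancer-registry
    case listings, developed around Hodgkin lymphoma. Provides
    month-length adjustment and standardization of monthly diagnosis
    counts, single-component cosinor rhythmometry with amplitude and
    acrophase inference and a group-amplitude comparison, a Cox
    proportional-hazards fitter built on the Efron/Breslow partial
    likelihood, a sinusoid seasonal-risk covariate with an iterative
    peak-risk-month scan, latitude-by-season interaction models, and a
    seeded synthetic registry generator so every pipeline stage can be
    exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    survival,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
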