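Package: tumorgrowth
Title: Fitting and Benchmarking Classical Tumor Growth Models on Longitudinal Lesion Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting six classical ordinary-differential-equation
    models of tumor growth (exponential, logistic, Gompertz, general Gompertz,
    classic and general von Bertalanffy) to longitudinal target-lesion
    longest-diameter measurements from clinical trials. Includes preprocessing
    (diameter-to-volume conversion, cohort-wide normalization, target-lesion
    selection, series-length filtering), RECIST and trajectory-type response
    classification with concordance analysis, global-plus-local parameter
    estimation (differential evolution seeding bounded least squares),
    goodness-of-fit and information-criterion model comparison, holdout
    forecasting of late measurements, and a synthetic-cohort generator that
    emulates the visit structure and measurement noise of clinical
    target-lesion data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
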