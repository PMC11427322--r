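Package: restorevis
Title: Visual Properties and Perceived Restorativeness of Indoor Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies visual properties of indoor (office) photographs --
    green-area percentage by HSV thresholding, box-counting and differential
    box-counting fractal dimensions, a colour fractal dimension, and 1/f
    spectral-slope fluctuation indices -- scores the 11-item Indoor
    Restorative Characteristic Scale (IRCS), and links the two with a
    reproducible statistical chain: per-column standardization, iterative
    VIF pruning with a protected predictor, a fixed-seed train/test split,
    10-fold cross-validated lasso regression with the one-standard-error
    rule, and RMSE evaluation. Ships published model coefficients as a
    data asset and a synthetic-data module that generates analytic fractal
    fixtures, office-like scenes with controllable greenery, and grouped
    Likert ratings with planted effect structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    glmnet,
    jsonlite,
    png,
    tibble,
    dplyr,
    withr,
    rlang
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
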