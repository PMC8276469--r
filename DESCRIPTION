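Package: dentage
Title: Dental Age Estimation with Willems-Style Score Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for forensic dental age estimation from Demirjian
    developmental stages of the seven lower-left permanent mandibular teeth
    (FDI 31-37). Implements the Willems-style additive score-table predictor,
    fitting of population-specific coefficient tables by weighted analysis of
    variance with sex- and age-stratified train/test splits, and a validation
    toolkit (mean error, mean absolute error, RMSE with bootstrap confidence
    intervals, exact and approximate Wilcoxon signed-rank tests, calibration
    slope, and weighted kappa for observer agreement). Ships a coefficient
    table for Saudi Arabian children transcribed from published work, and a
    latent-maturation simulator that generates staged cohorts with ordinal
    stages monotone in age for testing the full workflow when radiograph data
    are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
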