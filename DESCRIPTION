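Package: operamd
Title: Risk Discrimination for Multi-Threshold Mammographic Density via OPERA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing mammographic-density measures defined at
    increasing pixel-brightness thresholds (conventional, higher, and highest
    -- the Cumulus, Altocumulus and Cirrocumulus family) as predictors of
    interval versus screen-detected breast cancer. Implements dual-threshold
    density measurement on grayscale images, Box-Cox transformation with
    covariate residualization and adjusted-standard-deviation scaling,
    conditional logistic regression for 1:M matched sets with likelihood-ratio
    testing, the odds-ratio-per-adjusted-standard-deviation (OPERA) framework
    with inter-quartile risk ratios, BIC posterior-odds model comparison,
    covariate-adjusted AUC, repeatability intraclass correlation, and a
    synthetic nested case-control cohort generator with an exact
    conditional-logistic data-generating mechanism for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    MASS,
    png,
    survival,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
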