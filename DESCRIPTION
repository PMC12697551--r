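Package: refcal
Title: Conformal Calibration of Covariate-Dependent Reference Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates pre-fitted, covariate-dependent reference intervals
    (e.g. brain-chart centiles for MRI phenotypes across age and sex) to a new
    sample using split conformal prediction on lower and upper quantile
    residuals. Provides naive interval models (a Box-Cox t location-scale-shape
    regression and penalized additive quantile regression), comparator methods
    (refitting, location-scale batch harmonization, batch-adjusted
    distributional regression), a synthetic multi-site data generator, a
    resampling evaluation harness with false-positive-rate and positive-rate
    summaries, and a gridded exchange format so calibrated charts can be shared
    without the reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
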