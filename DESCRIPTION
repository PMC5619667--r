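Package: aodcal
Title: Two-Stage Calibration of Satellite Aerosol Optical Depth to
    Ground-Level PM2.5
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates daily fine-particle (PM2.5) concentration surfaces
    from 1 km satellite aerosol optical depth (AOD).  A first-stage linear
    mixed-effects model with day-specific random intercept and slopes
    calibrates the temporally varying PM2.5-AOD relationship against ground
    monitors, meteorology and land-use covariates; a second-stage monthly
    geographically weighted regression of the stage-one residuals on AOD
    captures the spatially varying part of the relationship.  Includes a
    synthetic-study generator with known ground truth for parameter-recovery
    testing, preprocessing rules (detection-limit filtering, Terra/Aqua AOD
    combination with cross-imputation, daytime meteorology averaging, buffer
    aggregation, nearest-neighbour assignment), 10-fold cross-validation
    metrics, and annual/seasonal trend summaries with percent-change
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
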