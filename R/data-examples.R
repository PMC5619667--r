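#' Annual mean PM2.5 estimates for a southeastern-US study region
#'
#' Annual mean satellite-estimated PM2.5 concentrations (ug/m3),
#' 2001--2010, for a ~600 x 600 km southeastern-US study domain and for the
#' Atlanta metropolitan area within it, from a 1 km two-stage AOD
#' calibration of the kind this package implements.  Used as the worked
#' example for [percent_change()]: the 2001-to-2010 change is about -20%
#' domain-wide and -23% for the metro area, with the sharp drop between
#' 2007 and 2008.
#'
#' @format data.frame with columns `year`, `domain`, `atlanta`.
#' @export
seus_annual_pm25 <- data.frame(
  year = 2001:2010,
  domain = c(13.97, 13.90, 13.35, 13.31, 15.19,
             13.73, 13.22, 11.34, 10.58, 11.22),
  atlanta = c(15.10, 14.64, 14.00, 14.54, 15.63,
              14.39, 14.14, 11.78, 10.98, 11.65)
)

#' Annual model-fitting and cross-validation statistics
#'
#' Published-scale annual validation statistics (2001--2010) for the same
#' southeastern-US two-stage calibration: coefficient of determination,
#' mean prediction error (ug/m3), root mean squared prediction error
#' (ug/m3) and relative accuracy (%), for model fitting and 10-fold
#' cross-validation.  Relative accuracy is
#' `100 * (1 - RMSPE / mean observed PM2.5)`, so the observed annual mean
#' can be back-solved from any row; observed annual means over the decade
#' ranged from 11.03 to 15.63 ug/m3.
#'
#' @format data.frame with columns `year`, `scope` (`"fitting"`/`"cv"`),
#'   `r2`, `mpe`, `rmspe`, `relative_accuracy`.
#' @export
seus_validation <- local({
  years <- 2001:2010
  fit <- data.frame(
    year = years, scope = "fitting",
    r2 = c(0.78, 0.84, 0.85, 0.85, 0.84, 0.85, 0.79, 0.74, 0.71, 0.73),
    mpe = c(2.50, 2.10, 1.95, 1.97, 2.23, 2.02, 2.26, 1.93, 1.73, 1.90),
    rmspe = c(4.10, 2.98, 2.77, 2.77, 3.17, 2.90, 3.75, 3.13, 2.88, 2.75),
    relative_accuracy = c(72.9, 80.7, 80.4, 80.3, 79.7, 80.6, 74.0, 75.4,
                          73.9, 77.6)
  )
  cv <- data.frame(
    year = years, scope = "cv",
    r2 = c(0.67, 0.75, 0.76, 0.77, 0.78, 0.78, 0.71, 0.67, 0.62, 0.66),
    mpe = c(3.01, 2.62, 2.42, 2.40, 2.64, 2.43, 2.64, 2.21, 2.00, 2.15),
    rmspe = c(5.00, 3.75, 3.47, 3.37, 3.76, 3.49, 4.39, 3.53, 3.28, 3.12),
    relative_accuracy = c(67.0, 75.7, 75.4, 76.1, 75.9, 76.6, 69.6, 72.3,
                          70.3, 74.5)
  )
  rbind(fit, cv)
})
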