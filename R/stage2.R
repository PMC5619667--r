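#' Specification of the stage-2 geographically weighted regression
#'
#' The stage-2 model regresses monthly pooled stage-1 residuals on AOD with
#' kernel-weighted local least squares, yielding a location-specific
#' intercept and slope at every target (monitor or prediction cell).
#'
#' @param kernel `"gaussian"` (default) or `"bisquare"`; distance-based
#'   fixed bandwidth.
#' @param bandwidth kernel bandwidth in km, or `"auto"` to select by
#'   leave-one-site-out cross-validation ([select_bandwidth()]).
#' @param min_local_points minimum site-day records a month must have to be
#'   fitted; months below it are flagged and fall back to stage 1.
#' @param monthly_mean if `TRUE`, collapse each site's month to its mean
#'   residual and mean AOD before fitting (one point per site-month)
#'   instead of pooling daily records.
#' @return object of class `gwr_spec`.
#' @export
gwr_spec <- function(kernel = c("gaussian", "bisquare"),
                     bandwidth = "auto",
                     min_local_points = 10L,
                     monthly_mean = FALSE) {
  kernel <- match.arg(kernel)
  if (is.numeric(bandwidth)) {
    stopifnot(bandwidth > 0)
  } else if (!identical(bandwidth, "auto")) {
    stop("bandwidth must be a positive number or \"auto\"")
  }
  stopifnot(min_local_points >= 3L)
  structure(list(kernel = kernel, bandwidth = bandwidth,
                 min_local_points = as.integer(min_local_points),
                 monthly_mean = isTRUE(monthly_mean)),
            class = "gwr_spec")
}

#' Kernel weights for GWR
#'
#' Gaussian: `exp(-d^2 / (2 h^2))`; bisquare: `(1 - (d/h)^2)^2` inside the
#' bandwidth, 0 outside.  Weights are 1 at zero distance and non-increasing
#' in distance; an infinite bandwidth gives unit weights (global OLS).
#'
#' @param d nonnegative distances (km).
#' @param bandwidth kernel bandwidth h (km); may be `Inf`.
#' @param kernel `"gaussian"` or `"bisquare"`.
#' @return weights the same shape as `d`.
#' @export
kernel_weights <- function(d, bandwidth, kernel = "gaussian") {
  if (is.infinite(bandwidth)) {
    w <- d * 0 + 1
    return(w)
  }
  switch(kernel,
         gaussian = exp(-d^2 / (2 * bandwidth^2)),
         bisquare = ifelse(d < bandwidth, (1 - (d / bandwidth)^2)^2, 0),
         stop("unknown kernel: ", kernel))
}

# Collapse daily site records to site-month means when requested.
gwr_month_data <- function(data, spec) {
  if (!spec$monthly_mean) return(data)
  agg <- stats::aggregate(data[, c("x", "y", "aod", "resid")],
                          by = list(site_id = data$site_id), FUN = mean)
  agg
}

#' Fit the GWR for one month
#'
#' At each target location, solves the weighted least-squares regression of
#' the month's pooled stage-1 residuals on AOD, with kernel weights on the
#' site-target distance.  Targets whose local design is degenerate (kernel
#' mass concentrated on effectively constant AOD) are flagged and assigned
#' the locally weighted mean residual with zero slope.
#'
#' @param data data.frame of one month's site-day records: `site_id`, `x`,
#'   `y`, `aod`, `resid`.
#' @param targets data.frame of target locations: `loc_id`, `x`, `y`.
#' @param spec a [gwr_spec()].
#' @param bandwidth numeric bandwidth (km); overrides `spec$bandwidth`.
#' @return data.frame `loc_id`, `x`, `y`, `beta0`, `beta1`, `flagged`, with
#'   attributes `bandwidth` and `n_points`.
#' @export
fit_gwr_month <- function(data, targets, spec = gwr_spec(), bandwidth = NULL) {
  stopifnot(all(c("x", "y", "aod", "resid") %in% names(data)),
            all(c("loc_id", "x", "y") %in% names(targets)))
  data <- gwr_month_data(data, spec)
  if (nrow(data) < spec$min_local_points) {
    stop("month has ", nrow(data), " records; need >= ", spec$min_local_points)
  }
  h <- if (!is.null(bandwidth)) bandwidth else spec$bandwidth
  if (!is.numeric(h)) {
    stop("bandwidth is \"auto\"; run select_bandwidth() first or pass a number")
  }
  co <- gwr_coefficients(
    tx = targets$x, ty = targets$y,
    px = data$x, py = data$y, aod = data$aod, y = data$resid,
    bandwidth = h, kernel = spec$kernel
  )
  n_flagged <- sum(co$flagged)
  if (n_flagged > 0) {
    warning(n_flagged, " target(s) had a rank-deficient local design; ",
            "assigned (local mean residual, 0)")
  }
  out <- data.frame(loc_id = targets$loc_id, x = targets$x, y = targets$y,
                    beta0 = co$beta0, beta1 = co$beta1, flagged = co$flagged)
  attr(out, "bandwidth") <- h
  attr(out, "n_points") <- nrow(data)
  out
}

# Vectorised local WLS of y on aod at each target; closed-form 2x2 normal
# equations.  `drop_site` optionally zeroes the weights of one site per
# target row (leave-one-site-out), given as a site factor per point and a
# site per target.
gwr_coefficients <- function(tx, ty, px, py, aod, y, bandwidth, kernel,
                             point_site = NULL, target_site = NULL) {
  d <- sqrt(outer(tx, px, "-")^2 + outer(ty, py, "-")^2)
  W <- kernel_weights(d, bandwidth, kernel)
  if (!is.null(point_site)) {
    W[outer(target_site, point_site, "==")] <- 0
  }
  sw <- drop(W %*% rep(1, length(px)))
  swx <- drop(W %*% aod)
  swx2 <- drop(W %*% aod^2)
  swy <- drop(W %*% y)
  swxy <- drop(W %*% (aod * y))
  varw <- swx2 / sw - (swx / sw)^2
  scale2 <- max(mean(aod^2), .Machine$double.eps)
  degenerate <- !is.finite(varw) | varw <= 1e-10 * scale2 | sw <= 0
  beta1 <- ifelse(degenerate, 0,
                  (sw * swxy - swx * swy) / (sw * swx2 - swx^2))
  beta0 <- ifelse(sw > 0, (swy - beta1 * swx) / sw, mean(y))
  list(beta0 = beta0, beta1 = beta1, flagged = degenerate)
}

#' Select the GWR bandwidth by leave-one-site-out cross-validation
#'
#' For each candidate bandwidth, each month and each monitor site, fits the
#' local regression at the site's location using every other site's records
#' of that month, predicts the held-out site's residuals from its AOD, and
#' accumulates squared errors over all months.  The bandwidth minimising
#' the pooled RMSE is returned; a score profile monotone to the grid edge
#' triggers a warning and returns the edge value.
#'
#' @param resid_df site-day records across one or more months: `site_id`,
#'   `month`, `x`, `y`, `aod`, `resid`.
#' @param spec a [gwr_spec()].
#' @param candidates numeric candidate bandwidths (km); default a 10-point
#'   log-spaced grid from 5% to 200% of the domain extent.
#' @return the selected bandwidth, with attribute `"profile"` (a data.frame
#'   of candidate and CV RMSE).
#' @export
select_bandwidth <- function(resid_df, spec = gwr_spec(), candidates = NULL) {
  stopifnot(all(c("site_id", "month", "x", "y", "aod", "resid") %in%
                  names(resid_df)))
  if (is.null(candidates)) {
    extent <- max(diff(range(resid_df$x)), diff(range(resid_df$y)), 1)
    candidates <- exp(seq(log(0.05 * extent), log(2 * extent), length.out = 10))
  }
  candidates <- sort(unique(candidates))
  if (length(candidates) == 1L) return(candidates)

  months <- split(resid_df, resid_df$month)
  months <- Filter(function(m) nrow(m) >= spec$min_local_points &&
                     length(unique(m$site_id)) >= 2L, months)
  if (length(months) == 0) stop("no month has enough records for bandwidth CV")

  score <- vapply(candidates, function(h) {
    sse <- 0; n <- 0L
    for (m in months) {
      md <- gwr_month_data(m, spec)
      sites <- unique(m$site_id)
      sxy <- m[match(sites, m$site_id), c("x", "y")]
      co <- gwr_coefficients(
        tx = sxy$x, ty = sxy$y,
        px = md$x, py = md$y, aod = md$aod, y = md$resid,
        bandwidth = h, kernel = spec$kernel,
        point_site = md$site_id, target_site = sites
      )
      i <- match(m$site_id, sites)
      pred <- co$beta0[i] + co$beta1[i] * m$aod
      ok <- !co$flagged[i] & is.finite(pred)
      sse <- sse + sum((m$resid[ok] - pred[ok])^2)
      n <- n + sum(ok)
    }
    sqrt(sse / max(n, 1L))
  }, numeric(1))

  best <- which.min(score)
  if (best == 1L || best == length(candidates)) {
    warning("bandwidth CV profile is minimised at the grid edge (",
            signif(candidates[best], 3), " km)")
  }
  structure(candidates[best],
            profile = data.frame(bandwidth = candidates, cv_rmse = score))
}

#' Fit monthly GWR surfaces for a set of months
#'
#' Splits the residual records by calendar month and fits [fit_gwr_month()]
#' at the given targets for each month with enough data; months below
#' `min_local_points` are flagged (recorded, not silently filled) and later
#' fall back to stage-1-only predictions.
#'
#' @param resid_df site-day records: `site_id`, `month`, `x`, `y`, `aod`,
#'   `resid`.
#' @param targets data.frame `loc_id`, `x`, `y`.
#' @param spec a [gwr_spec()].
#' @param bandwidth numeric bandwidth; if `NULL` and `spec$bandwidth` is
#'   `"auto"`, selected once on the pooled months via [select_bandwidth()].
#' @return object of class `stage2_fit`: list with `months` (named list of
#'   per-month coefficient data.frames), `skipped_months`, `bandwidth`,
#'   `spec`.
#' @export
fit_stage2 <- function(resid_df, targets, spec = gwr_spec(),
                       bandwidth = NULL) {
  if (is.null(bandwidth)) {
    bandwidth <- if (is.numeric(spec$bandwidth)) {
      spec$bandwidth
    } else {
      as.numeric(select_bandwidth(resid_df, spec))
    }
  }
  by_month <- split(resid_df, resid_df$month)
  fits <- list(); skipped <- character()
  for (mon in names(by_month)) {
    md <- by_month[[mon]]
    if (nrow(gwr_month_data(md, spec)) < spec$min_local_points) {
      skipped <- c(skipped, mon)
      next
    }
    fits[[mon]] <- fit_gwr_month(md, targets, spec, bandwidth = bandwidth)
  }
  structure(list(months = fits, skipped_months = skipped,
                 bandwidth = bandwidth, spec = spec),
            class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat("Stage-2 monthly GWR fit\n")
  cat(sprintf("  months fitted: %d (skipped: %d); bandwidth %.2f km (%s)\n",
              length(x$months), length(x$skipped_months),
              x$bandwidth, x$spec$kernel))
  invisible(x)
}

#' Apply the stage-2 residual correction
#'
#' Final estimate = stage-1 prediction + `beta0(cell) + beta1(cell) * AOD`
#' for the cell's month.  Rows whose month was skipped in stage 2 (or whose
#' target was flagged) fall back to the stage-1 prediction; provenance is
#' recorded per row.  Rows with missing AOD yield no prediction (dropped).
#' Final estimates are floored at 0; the number of floored rows is in the
#' `"n_floored"` attribute.
#'
#' @param pred1_df data.frame with `loc_id`, `date`, `aod`, `pred1`
#'   (stage-1 prediction).
#' @param stage2_fit a [fit_stage2()] result whose targets cover the
#'   `loc_id`s.
#' @return data.frame `loc_id`, `date`, `pred` (final), `pred1`,
#'   `provenance` (`"two_stage"` or `"stage1_only"`).
#' @export
predict_stage2 <- function(pred1_df, stage2_fit) {
  stopifnot(inherits(stage2_fit, "stage2_fit"),
            all(c("loc_id", "date", "aod", "pred1") %in% names(pred1_df)))
  df <- pred1_df[!is.na(pred1_df$aod), , drop = FALSE]
  df$month <- substr(as.character(df$date), 1L, 7L)
  pred <- df$pred1
  provenance <- rep("stage1_only", nrow(df))
  for (mon in names(stage2_fit$months)) {
    co <- stage2_fit$months[[mon]]
    rows <- which(df$month == mon)
    if (length(rows) == 0) next
    i <- match(df$loc_id[rows], co$loc_id)
    ok <- !is.na(i)
    ok[ok] <- !co$flagged[i[ok]]
    use <- rows[ok]
    iu <- i[ok]
    pred[use] <- df$pred1[use] + co$beta0[iu] + co$beta1[iu] * df$aod[use]
    provenance[use] <- "two_stage"
  }
  floored <- pred < 0
  pred[floored] <- 0
  out <- data.frame(loc_id = df$loc_id, date = df$date, pred = pred,
                    pred1 = df$pred1, provenance = provenance,
                    stringsAsFactors = FALSE)
  attr(out, "n_floored") <- sum(floored)
  out
}
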