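#' Discard PM2.5 values below the detection limit
#'
#' Removes records with concentrations strictly below `limit` (default
#' 2 ug/m3, the established detection limit of 24 h filter-based reference
#' monitors).  The removed fraction is recorded in the `"removed_fraction"`
#' attribute.
#'
#' @param records data.frame with a numeric `pm25` column.
#' @param limit detection limit in ug/m3; values `< limit` are dropped.
#' @return the filtered data.frame.
#' @export
filter_pm25 <- function(records, limit = 2) {
  stopifnot(is.data.frame(records), "pm25" %in% names(records),
            is.numeric(records$pm25))
  n0 <- nrow(records)
  keep <- is.na(records$pm25) | records$pm25 >= limit
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_fraction") <- if (n0 > 0) (n0 - nrow(out)) / n0 else 0
  out
}

#' Fit the Terra--Aqua daily-mean AOD link
#'
#' Per calendar year, regresses the domain daily-mean Terra AOD on the
#' daily-mean Aqua AOD by OLS, and vice versa, over days on which both
#' satellites have at least one retrieval.  The fitted lines are later used
#' to cross-impute the satellite missing on a given cell-day.
#'
#' @param env long data.frame with `date`, `aod_terra`, `aod_aqua` columns
#'   (site- or cell-level rows).
#' @param min_days minimum number of complete days required per year.
#' @return object of class `satellite_link`: a list keyed by year, each with
#'   `terra_on_aqua` and `aqua_on_terra` coefficient vectors
#'   `(intercept, slope)` and the number of days used.
#' @export
fit_satellite_link <- function(env, min_days = 10L) {
  stopifnot(all(c("date", "aod_terra", "aod_aqua") %in% names(env)))
  year <- substr(as.character(env$date), 1L, 4L)
  link <- lapply(split(env, year), function(df) {
    tm <- tapply(df$aod_terra, df$date, mean, na.rm = TRUE)
    am <- tapply(df$aod_aqua, df$date, mean, na.rm = TRUE)
    ok <- is.finite(tm) & is.finite(am)
    yr <- substr(df$date[1L], 1L, 4L)
    if (sum(ok) < min_days) {
      stop("satellite link for year ", yr, ": only ", sum(ok),
           " days with both daily means (need >= ", min_days, ")")
    }
    tm <- tm[ok]; am <- am[ok]
    if (stats::sd(am) < 1e-12 || stats::sd(tm) < 1e-12) {
      stop("satellite link for year ", yr,
           ": degenerate regression (constant daily means)")
    }
    t_on_a <- stats::coef(stats::lm(tm ~ am))
    a_on_t <- stats::coef(stats::lm(am ~ tm))
    list(terra_on_aqua = stats::setNames(as.numeric(t_on_a),
                                         c("intercept", "slope")),
         aqua_on_terra = stats::setNames(as.numeric(a_on_t),
                                         c("intercept", "slope")),
         n_days = sum(ok))
  })
  structure(link, class = "satellite_link")
}

#' Combine Terra and Aqua AOD into a daily value
#'
#' Cell-days with both retrievals get their average.  Cell-days with one
#' retrieval get the average of the observed value and its cross-prediction
#' through the year's [fit_satellite_link()] line, so the combined value
#' always represents a morning/afternoon mean.  Combined values above
#' `upper_bound` (default 2.0, guarding against residual cloud
#' contamination) are set missing; the excluded fraction is recorded in the
#' `"excluded_fraction"` attribute.
#'
#' @param env long data.frame with `date`, `aod_terra`, `aod_aqua`.
#' @param link a `satellite_link`.
#' @param upper_bound exclusion threshold for the combined AOD.
#' @return `env` with an `aod_combined` column added.
#' @export
combine_aod <- function(env, link, upper_bound = 2.0) {
  stopifnot(inherits(link, "satellite_link"))
  year <- substr(as.character(env$date), 1L, 4L)
  missing_years <- setdiff(unique(year), names(link))
  if (length(missing_years) > 0) {
    stop("no satellite link fitted for year(s): ",
         paste(missing_years, collapse = ", "))
  }
  te <- env$aod_terra
  aq <- env$aod_aqua
  comb <- rep(NA_real_, nrow(env))
  both <- !is.na(te) & !is.na(aq)
  comb[both] <- (te[both] + aq[both]) / 2
  for (yr in names(link)) {
    l <- link[[yr]]
    i_t <- year == yr & !is.na(te) & is.na(aq)
    comb[i_t] <- (te[i_t] +
                    (l$aqua_on_terra[["intercept"]] +
                       l$aqua_on_terra[["slope"]] * te[i_t])) / 2
    i_a <- year == yr & is.na(te) & !is.na(aq)
    comb[i_a] <- (aq[i_a] +
                    (l$terra_on_aqua[["intercept"]] +
                       l$terra_on_aqua[["slope"]] * aq[i_a])) / 2
  }
  over <- !is.na(comb) & comb > upper_bound
  n_present <- sum(!is.na(comb))
  comb[over] <- NA_real_
  env$aod_combined <- comb
  attr(env, "excluded_fraction") <- if (n_present > 0) sum(over) / n_present else 0
  env
}

#' Average sub-daily meteorology over the daytime window
#'
#' Computes the per location-day arithmetic mean of each meteorological
#' variable over local timestamps in the closed window `[10:00, 16:00]`,
#' matching the satellite morning/afternoon overpass period.  Days with no
#' timestamps in the window yield `NA`.
#'
#' @param hourly data.frame with `loc_id`, `date`, `hour` and one or more
#'   numeric value columns.
#' @param window closed hour window, default `c(10, 16)`.
#' @return data.frame with one row per (loc_id, date) present in `hourly`
#'   and the window means of every value column.
#' @export
average_daytime_met <- function(hourly, window = c(10, 16)) {
  need <- c("loc_id", "date", "hour")
  stopifnot(all(need %in% names(hourly)))
  vars <- setdiff(names(hourly), need)
  stopifnot(length(vars) > 0)
  keys <- unique(hourly[, c("loc_id", "date")])
  sub <- hourly[hourly$hour >= window[1L] & hourly$hour <= window[2L], ,
                drop = FALSE]
  agg <- stats::aggregate(sub[vars], by = sub[c("loc_id", "date")],
                          FUN = mean)
  out <- merge(keys, agg, by = c("loc_id", "date"), all.x = TRUE,
               sort = FALSE)
  out[order(out$loc_id, out$date), , drop = FALSE]
}

#' Aggregate raw covariate samples over a square buffer
#'
#' Applies the buffer rules of site-level land-use integration over the
#' axis-aligned square of side `cell_size_km` centred at `location`:
#' elevation and forest cover are averaged, road length and point emissions
#' are summed, and empty sums are zero (cells with no roads or emission
#' sources carry zeros, not missing values).
#'
#' @param raw data.frame of sub-cell samples with `x`, `y` and any of
#'   `elevation`, `forest_cover` (averaged) and `road_length`,
#'   `point_emissions` (summed).
#' @param location numeric `(x, y)` of the buffer centre (km).
#' @param cell_size_km buffer side length (km).
#' @return one-row data.frame of aggregated covariates.
#' @export
aggregate_buffer <- function(raw, location, cell_size_km = 1) {
  stopifnot(all(c("x", "y") %in% names(raw)), length(location) == 2L)
  half <- cell_size_km / 2
  inside <- abs(raw$x - location[1L]) <= half &
    abs(raw$y - location[2L]) <= half
  sub <- raw[inside, , drop = FALSE]
  out <- list()
  for (v in intersect(c("elevation", "forest_cover"), names(raw))) {
    vals <- sub[[v]][!is.na(sub[[v]])]
    if (length(vals) == 0) {
      stop("no ", v, " samples in the buffer at (",
           location[1L], ", ", location[2L], "); mean undefined")
    }
    out[[v]] <- mean(vals)
  }
  for (v in intersect(c("road_length", "point_emissions"), names(raw))) {
    vals <- sub[[v]][!is.na(sub[[v]])]
    out[[v]] <- sum(vals)                 # empty -> 0
  }
  as.data.frame(out)
}

#' Assign a field value to a location by nearest neighbour
#'
#' Returns the value at the Euclidean-nearest field node, ties broken by the
#' lowest node id.  If the nearest node's value is missing that day the
#' result is missing -- no fallback to farther non-missing nodes, so AOD
#' coverage is never artificially extended.
#'
#' @param field data.frame with `loc_id`, `x`, `y`, `value`.
#' @param location numeric `(x, y)`.
#' @return scalar value (possibly `NA`).
#' @export
assign_nearest <- function(field, location) {
  stopifnot(all(c("loc_id", "x", "y", "value") %in% names(field)),
            nrow(field) >= 1L, length(location) == 2L)
  d2 <- (field$x - location[1L])^2 + (field$y - location[2L])^2
  ord <- order(d2, field$loc_id)
  field$value[ord[1L]]
}

#' Build the analysis-ready site-day table
#'
#' Inner-joins monitor observations with site-level daily environment
#' (combined AOD and meteorology) and static site covariates, then drops
#' rows with any missing predictor.  Drop counts by cause are recorded in
#' the `"report"` attribute.  Only AOD is ever imputed upstream (via
#' [combine_aod()]); PM2.5 is never imputed.
#'
#' @param observations data.frame `site_id`, `date`, `pm25` (already
#'   filtered by [filter_pm25()]); `(site_id, date)` must be unique.
#' @param env site-level data.frame `loc_id` (= site_id), `date`,
#'   `aod_combined` and meteorology columns.
#' @param covariates data.frame `site_id` (or `cell_id`), `x`, `y`,
#'   `elevation`, `forest_cover`, `road_length`, `point_emissions`.
#' @return data.frame with one row per retained site-day: `site_id`, `date`,
#'   `year`, `month`, `x`, `y`, `pm25`, `aod`, meteorology and covariate
#'   columns.
#' @export
build_analysis_table <- function(observations, env, covariates) {
  stopifnot(all(c("site_id", "date", "pm25") %in% names(observations)))
  key <- paste(observations$site_id, observations$date)
  if (anyDuplicated(key)) {
    stop("duplicated (site_id, date) in observations: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  }
  ekey <- paste(env$loc_id, env$date)
  if (anyDuplicated(ekey)) stop("duplicated (loc_id, date) in env")
  if (!"site_id" %in% names(covariates)) {
    stop("covariates must carry a site_id column")
  }

  met_cols <- intersect(c("rh", "blh", "u_wind", "v_wind", "wind_speed"),
                        names(env))
  if (!"aod_combined" %in% names(env)) {
    stop("env must carry aod_combined (run combine_aod() first)")
  }
  cov_cols <- c("elevation", "forest_cover", "road_length", "point_emissions")
  stopifnot(all(cov_cols %in% names(covariates)),
            all(c("x", "y") %in% names(covariates)))

  tab <- merge(observations,
               env[, c("loc_id", "date", "aod_combined", met_cols)],
               by.x = c("site_id", "date"), by.y = c("loc_id", "date"))
  tab <- merge(tab, covariates[, c("site_id", "x", "y", cov_cols)],
               by = "site_id")
  n_joined <- nrow(tab)

  miss_aod <- is.na(tab$aod_combined)
  miss_met <- rowSums(is.na(tab[, met_cols, drop = FALSE])) > 0
  miss_cov <- rowSums(is.na(tab[, cov_cols, drop = FALSE])) > 0
  keep <- !(miss_aod | miss_met | miss_cov)
  report <- list(
    n_observations = nrow(observations),
    n_joined = n_joined,
    dropped_missing_aod = sum(miss_aod),
    dropped_missing_met = sum(miss_met & !miss_aod),
    dropped_missing_covariate = sum(miss_cov & !miss_aod & !miss_met),
    n_retained = sum(keep)
  )
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("analysis table is empty after dropping missing rows")

  names(tab)[names(tab) == "aod_combined"] <- "aod"
  tab$year <- substr(as.character(tab$date), 1L, 4L)
  tab$month <- substr(as.character(tab$date), 1L, 7L)
  tab <- tab[order(tab$site_id, tab$date),
             c("site_id", "date", "year", "month", "x", "y", "pm25", "aod",
               met_cols, cov_cols)]
  rownames(tab) <- NULL
  attr(tab, "report") <- report
  tab
}

#' Prepare a synthetic study for model fitting
#'
#' Convenience wrapper: filters monitor PM2.5 below the detection limit,
#' fits the annual Terra--Aqua link on the full gridded environment,
#' combines the satellites' AOD (with the 2.0 upper bound), extracts the
#' site-level environment (monitors sit at cell centres, so the nearest
#' grid node is the monitor's own cell) and builds the analysis table.
#'
#' @param study a complete `synth_study`.
#' @param pm25_limit detection limit passed to [filter_pm25()].
#' @param min_link_days minimum complete days for [fit_satellite_link()].
#' @return list with `table` (analysis table), `env` (gridded environment
#'   with `aod_combined`), `link`, and `report` (drop accounting).
#' @export
prepare_study <- function(study, pm25_limit = 2, min_link_days = 10L) {
  stopifnot(inherits(study, "synth_study"), !is.null(study$observations))
  obs <- filter_pm25(study$observations, limit = pm25_limit)

  # fit the Terra--Aqua link per year; a year without enough coverage is
  # excluded (its combined AOD stays missing) rather than aborting the run
  years <- unique(substr(study$env$date, 1L, 4L))
  link <- list()
  for (yr in years) {
    sub <- study$env[substr(study$env$date, 1L, 4L) == yr, , drop = FALSE]
    l <- tryCatch(fit_satellite_link(sub, min_days = min_link_days),
                  error = function(e) {
                    warning("year ", yr, " excluded from AOD combination: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(l)) link[[yr]] <- l[[yr]]
  }
  if (length(link) == 0) stop("no year has enough Terra/Aqua coverage")
  class(link) <- "satellite_link"

  ok <- substr(study$env$date, 1L, 4L) %in% names(link)
  env <- study$env
  env$aod_combined <- NA_real_
  combined <- combine_aod(study$env[ok, , drop = FALSE], link)
  env$aod_combined[ok] <- combined$aod_combined
  attr(env, "excluded_fraction") <- attr(combined, "excluded_fraction")

  site_env <- env[env$loc_id %in% study$monitors$cell_id, , drop = FALSE]
  idx <- match(site_env$loc_id, study$monitors$cell_id)
  site_env$loc_id <- study$monitors$site_id[idx]

  covs <- study$monitors
  tab <- build_analysis_table(obs, site_env, covs)
  report <- attr(tab, "report")
  report$pm25_removed_fraction <- attr(obs, "removed_fraction")
  report$aod_excluded_fraction <- attr(env, "excluded_fraction")
  list(table = tab, env = env, link = link, report = report)
}
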