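season_of <- function(dates) {
  m <- as.integer(substr(as.character(dates), 6L, 7L))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

in_region <- function(x, y, region) {
  if (is.null(region)) return(rep(TRUE, length(x)))
  stopifnot(length(region) == 4L)           # xmin, xmax, ymin, ymax
  x >= region[1L] & x <= region[2L] & y >= region[3L] & y <= region[4L]
}

#' Period mean of daily gridded predictions
#'
#' Averages daily cell-level predictions over a year (optionally one
#' meteorological season) and a rectangular sub-region.  Cells with fewer
#' than `min_coverage` of the period's prediction days are excluded from
#' the region mean (equal-cell weighting; cells are equal-area).
#'
#' @param pred data.frame of daily predictions: `loc_id`, `x`, `y`, `date`,
#'   `pred`.
#' @param year calendar year (integer or string).
#' @param season optional `"DJF"`, `"MAM"`, `"JJA"` or `"SON"`.
#' @param region optional bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @param min_coverage minimum fraction of the period's days a cell must
#'   have predictions for.
#' @return object of class `period_summary`: list with `cells` (per-cell
#'   means and day counts), `mean` (region mean over included cells),
#'   `year`, `season`, `n_dates`.
#' @export
period_mean <- function(pred, year, season = NULL, region = NULL,
                        min_coverage = 0.1) {
  stopifnot(all(c("loc_id", "x", "y", "date", "pred") %in% names(pred)))
  sel <- substr(as.character(pred$date), 1L, 4L) == as.character(year) &
    in_region(pred$x, pred$y, region)
  if (!is.null(season)) sel <- sel & season_of(pred$date) == season
  sub <- pred[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no predictions in year ", year,
         if (!is.null(season)) paste0(" season ", season))
  }
  n_dates <- length(unique(sub$date))
  agg <- stats::aggregate(
    list(mean = sub$pred, n = rep(1L, nrow(sub))),
    by = list(loc_id = sub$loc_id), FUN = sum)
  agg$mean <- agg$mean / agg$n
  i <- match(agg$loc_id, sub$loc_id)
  cells <- data.frame(loc_id = agg$loc_id, x = sub$x[i], y = sub$y[i],
                      mean = agg$mean, n = agg$n,
                      included = agg$n >= min_coverage * n_dates)
  structure(list(cells = cells,
                 mean = mean(cells$mean[cells$included]),
                 year = as.integer(year), season = season,
                 n_dates = n_dates),
            class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("Period mean PM2.5, %d%s: %.2f ug/m3 over %d cells (%d days)\n",
              x$year, if (is.null(x$season)) "" else paste0(" ", x$season),
              x$mean, sum(x$cells$included), x$n_dates))
  invisible(x)
}

#' Percent change of PM2.5 between two periods
#'
#' Applies `100 * (end - start) / start`.  For plain numbers the formula is
#' vectorised (non-positive starts give `NA`).  For two [period_mean()]
#' summaries it is applied per cell (cells missing from either period, or
#' with non-positive start, are `NA` -- never zero) and to the region
#' means; the reported region change applies the formula to the region
#' means, with the mean of the per-cell changes also returned.
#'
#' @param start,end numbers, or two `period_summary` objects on matching
#'   grids.
#' @param ... unused.
#' @return numeric vector, or an object of class `change_surface`: list
#'   with `cells` (per-cell percent change), `mean` (formula on region
#'   means), `cells_mean` (mean of per-cell changes), `start_year`,
#'   `end_year`.
#' @export
percent_change <- function(start, end, ...) UseMethod("percent_change")

#' @rdname percent_change
#' @export
percent_change.default <- function(start, end, ...) {
  ifelse(!is.na(start) & start > 0, (end - start) / start * 100, NA_real_)
}

#' @rdname percent_change
#' @export
percent_change.period_summary <- function(start, end, ...) {
  stopifnot(inherits(end, "period_summary"))
  ids <- union(start$cells$loc_id, end$cells$loc_id)
  i1 <- match(ids, start$cells$loc_id)
  i2 <- match(ids, end$cells$loc_id)
  s <- ifelse(!is.na(i1) & start$cells$included[pmax(i1, 1L)],
              start$cells$mean[pmax(i1, 1L)], NA_real_)
  e <- ifelse(!is.na(i2) & end$cells$included[pmax(i2, 1L)],
              end$cells$mean[pmax(i2, 1L)], NA_real_)
  pc <- ifelse(is.na(s) | is.na(e), NA_real_, percent_change.default(s, e))
  x <- ifelse(!is.na(i1), start$cells$x[pmax(i1, 1L)],
              end$cells$x[pmax(i2, 1L)])
  y <- ifelse(!is.na(i1), start$cells$y[pmax(i1, 1L)],
              end$cells$y[pmax(i2, 1L)])
  structure(list(
    cells = data.frame(loc_id = ids, x = x, y = y, percent_change = pc),
    mean = percent_change.default(start$mean, end$mean),
    cells_mean = mean(pc, na.rm = TRUE),
    start_year = start$year, end_year = end$year
  ), class = "change_surface")
}

#' @export
print.change_surface <- function(x, ...) {
  cat(sprintf("PM2.5 percent change %d -> %d: %.2f%% (region means); ",
              x$start_year, x$end_year, x$mean))
  cat(sprintf("mean of per-cell changes %.2f%%\n", x$cells_mean))
  invisible(x)
}

#' Annual and seasonal time series of estimated and observed PM2.5
#'
#' Builds three aligned series per year and per meteorological season
#' (DJF/MAM/JJA/SON, plus the full year as `"all"`): the region-wide mean
#' of gridded estimates, the mean of estimates sampled at monitor cells,
#' and the mean of monitor observations.  Because real monitor networks are
#' urban-biased, the region-wide series typically sits below the
#' monitor-based series.
#'
#' @param pred daily gridded predictions: `loc_id`, `x`, `y`, `date`,
#'   `pred`.
#' @param observations monitor records: `site_id`, `date`, `pm25`.
#' @param monitors monitor table with `site_id`, `cell_id`, `x`, `y`.
#' @param region optional bounding box `c(xmin, xmax, ymin, ymax)`.
#' @return data.frame with columns `year`, `season`, `est_domain`,
#'   `est_monitor`, `obs_monitor`, `n_cell_days`, `n_obs`.
#' @export
time_series_summary <- function(pred, observations, monitors,
                                region = NULL) {
  stopifnot(all(c("loc_id", "x", "y", "date", "pred") %in% names(pred)),
            all(c("site_id", "date", "pm25") %in% names(observations)),
            all(c("site_id", "cell_id") %in% names(monitors)))
  pred <- pred[in_region(pred$x, pred$y, region), , drop = FALSE]
  keep_sites <- monitors$site_id[
    monitors$cell_id %in% unique(pred$loc_id) |
      in_region(monitors$x, monitors$y, region)]
  obs <- observations[observations$site_id %in% keep_sites, , drop = FALSE]

  at_monitor <- pred$loc_id %in% monitors$cell_id
  pyear <- substr(as.character(pred$date), 1L, 4L)
  pseason <- season_of(pred$date)
  oyear <- substr(as.character(obs$date), 1L, 4L)
  oseason <- season_of(obs$date)

  rows <- list()
  for (yr in sort(unique(pyear))) {
    for (se in c("all", "DJF", "MAM", "JJA", "SON")) {
      pi <- pyear == yr & (se == "all" | pseason == se)
      oi <- oyear == yr & (se == "all" | oseason == se)
      if (!any(pi)) next
      rows[[length(rows) + 1L]] <- data.frame(
        year = as.integer(yr), season = se,
        est_domain = mean(pred$pred[pi]),
        est_monitor = if (any(pi & at_monitor)) {
          mean(pred$pred[pi & at_monitor])
        } else NA_real_,
        obs_monitor = if (any(oi)) mean(obs$pm25[oi]) else NA_real_,
        n_cell_days = sum(pi), n_obs = sum(oi)
      )
    }
  }
  do.call(rbind, rows)
}
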