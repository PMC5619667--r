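#' Configuration of a full pipeline run
#'
#' Bundles the synthetic-study configuration, the stage-1 and stage-2
#' specifications, cross-validation and trend settings, the output
#' directory and the single master seed from which all randomness in the
#' run flows (the synthesis seed is set from it, and the CV fold seed is
#' derived with a fixed offset so changing one does not perturb the other).
#'
#' @param synth a [domain_config()] (its `seed` is overridden by `seed`).
#' @param stage1 a [stage1_spec()] of candidate predictors.
#' @param gwr a [gwr_spec()].
#' @param cv list with `k` (folds) and optional `enabled` flag.
#' @param trends list with optional `region` box and `min_coverage`.
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param select run backward variable selection per year.
#' @param write_daily also write the (large) daily cell-level predictions.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = domain_config(),
                       stage1 = stage1_spec(),
                       gwr = gwr_spec(),
                       cv = list(k = 10L, enabled = TRUE),
                       trends = list(region = NULL, min_coverage = 0.1),
                       out_dir = file.path(tempdir(), "aodcal-run"),
                       seed = 1L,
                       select = TRUE,
                       write_daily = FALSE) {
  stopifnot(inherits(synth, "domain_config"),
            inherits(stage1, "stage1_spec"), inherits(gwr, "gwr_spec"))
  if (is.null(cv$k)) cv$k <- 10L
  if (is.null(cv$enabled)) cv$enabled <- TRUE
  if (is.null(trends$min_coverage)) trends$min_coverage <- 0.1
  structure(list(synth = synth, stage1 = stage1, gwr = gwr, cv = cv,
                 trends = trends, out_dir = out_dir,
                 seed = as.integer(seed), select = isTRUE(select),
                 write_daily = isTRUE(write_daily)),
            class = "run_config")
}

#' Run the full two-stage pipeline
#'
#' Per year: preprocess (detection-limit filter, satellite link, AOD
#' combination, analysis table) -> stage-1 LME (with optional backward
#' variable selection) -> residuals -> monthly stage-2 GWR coefficient
#' surfaces on the full grid -> daily grid predictions -> fitting metrics
#' and record-level k-fold CV -> annual means.  Across years: percent
#' change from the first to the last year and the annual/seasonal time
#' series.  All artifacts are written as CSV/JSON under `config$out_dir`;
#' the returned manifest records per-stage row counts, warnings, timing
#' and output checksums.  A year whose analysis table is empty (e.g. no
#' AOD coverage) is skipped with a warning.  Runs are deterministic given
#' the seed; the written manifest contains no wall-clock state.
#'
#' @param config a [run_config()].
#' @param study optionally, a pre-built `synth_study` to use instead of
#'   synthesising one from `config$synth`.
#' @return the run manifest (list), invisibly: config snapshot, package
#'   version, per-stage counts, per-year results (fit summaries, metrics,
#'   annual means), trends, warnings, timing and file checksums.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  warns <- character()
  note <- function(...) warns <<- c(warns, sprintf(...))

  if (is.null(study)) {
    scfg <- config$synth
    scfg$seed <- config$seed
    study <- synth_study(scfg)
  }
  prep <- prepare_study(study)
  tab_all <- prep$table
  env <- prep$env
  grid <- study$grid

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  years <- sort(unique(substr(study$truth$dates, 1L, 4L)))
  grid_targets <- data.frame(loc_id = grid$cell_id, x = grid$x, y = grid$y)
  cov_cols <- c("elevation", "forest_cover", "road_length", "point_emissions")

  all_pred <- list()
  year_results <- list()
  for (yi in seq_along(years)) {
    yr <- years[yi]
    tab <- tab_all[tab_all$year == yr, , drop = FALSE]
    if (nrow(tab) == 0) {
      warning("year ", yr, " has no usable records; skipped")
      note("year %s skipped: no usable records", yr)
      next
    }
    spec <- config$stage1
    if (config$select) {
      spec <- select_variables(tab, spec)
    }
    fit1 <- suppressWarnings(fit_stage1(tab, spec))
    rdf <- stage1_residuals(fit1, tab)

    bandwidth <- if (is.numeric(config$gwr$bandwidth)) {
      config$gwr$bandwidth
    } else {
      as.numeric(suppressWarnings(select_bandwidth(rdf, config$gwr)))
    }
    s2_grid <- suppressWarnings(
      fit_stage2(rdf, grid_targets, config$gwr, bandwidth = bandwidth))

    # daily grid predictions for cell-days with combined AOD
    genv <- env[substr(env$date, 1L, 4L) == yr & !is.na(env$aod_combined), ,
                drop = FALSE]
    gi <- match(genv$loc_id, grid$cell_id)
    newdata <- data.frame(
      date = genv$date, aod = genv$aod_combined,
      genv[, intersect(MET_FIELDS, names(genv)), drop = FALSE],
      grid[gi, cov_cols, drop = FALSE],
      row.names = NULL
    )
    p1 <- as.numeric(predict_stage1(fit1, newdata))
    p1df <- data.frame(loc_id = genv$loc_id, date = genv$date,
                       aod = genv$aod_combined, pred1 = p1)
    pred <- predict_stage2(p1df, s2_grid)
    pred$x <- grid$x[match(pred$loc_id, grid$cell_id)]
    pred$y <- grid$y[match(pred$loc_id, grid$cell_id)]
    all_pred[[yr]] <- pred

    # fitting metrics at monitor site-days (two-stage fitted values)
    site_p1df <- data.frame(loc_id = study$monitors$cell_id[
                              match(tab$site_id, study$monitors$site_id)],
                            date = tab$date, aod = tab$aod,
                            pred1 = rdf$pred1)
    site_fit <- predict_stage2(site_p1df, s2_grid)
    fit_metrics <- compute_metrics(site_fit$pred, tab$pm25, scope = "fitting")

    cv_res <- NULL
    if (isTRUE(config$cv$enabled) && nrow(tab) >= config$cv$k) {
      cv_res <- kfold_cv(tab, spec, config$gwr, k = config$cv$k,
                         seed = config$seed + 1000L + yi,
                         bandwidth = bandwidth)
    }

    annual <- period_mean(pred, yr, region = config$trends$region,
                          min_coverage = config$trends$min_coverage)
    year_results[[yr]] <- list(
      year = yr,
      spec = spec$fixed,
      eliminated = attr(spec, "eliminated"),
      fixed_effects = as.list(fit1$fixed),
      se = as.list(fit1$se),
      psi = unclass(fit1$psi),
      sigma2 = fit1$sigma2,
      n_obs = fit1$n_obs, n_days = fit1$n_days,
      bandwidth = bandwidth,
      skipped_months = s2_grid$skipped_months,
      fitting = unclass(fit_metrics),
      cv = if (!is.null(cv_res)) unclass(cv_res$report) else NULL,
      cv_stage1 = if (!is.null(cv_res)) unclass(cv_res$report_stage1) else NULL,
      annual_mean = annual$mean
    )
  }
  if (length(year_results) == 0) stop("no year produced any predictions")

  pred_all <- do.call(rbind, all_pred)
  rownames(pred_all) <- NULL
  ts <- time_series_summary(pred_all, study$observations, study$monitors,
                            region = config$trends$region)

  change <- NULL
  fitted_years <- names(year_results)
  if (length(fitted_years) >= 2L) {
    y1 <- fitted_years[1L]
    y2 <- fitted_years[length(fitted_years)]
    pm1 <- period_mean(pred_all, y1, region = config$trends$region,
                       min_coverage = config$trends$min_coverage)
    pm2 <- period_mean(pred_all, y2, region = config$trends$region,
                       min_coverage = config$trends$min_coverage)
    change <- percent_change(pm1, pm2)
    utils::write.csv(change$cells,
                     file.path(config$out_dir, "change_surface.csv"),
                     row.names = FALSE)
  }

  # annual per-cell means
  annual_cells <- do.call(rbind, lapply(fitted_years, function(yr) {
    pm <- period_mean(pred_all, yr, min_coverage = config$trends$min_coverage)
    cbind(year = as.integer(yr), pm$cells)
  }))
  utils::write.csv(annual_cells,
                   file.path(config$out_dir, "annual_cell_means.csv"),
                   row.names = FALSE)
  utils::write.csv(ts, file.path(config$out_dir, "time_series.csv"),
                   row.names = FALSE)
  if (config$write_daily) {
    utils::write.csv(pred_all,
                     file.path(config$out_dir, "daily_predictions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(year_results,
                       file.path(config$out_dir, "fit_summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(prep$report,
                       file.path(config$out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)

  manifest <- list(
    package_version = as.character(utils::packageVersion("aodcal")),
    seed = config$seed,
    synth = config$synth[c("domain_size_km", "cell_size_km", "n_monitors",
                           "n_days", "n_years", "start_year")],
    stage1_candidates = config$stage1$fixed,
    gwr = unclass(config$gwr),
    cv_k = config$cv$k,
    counts = list(
      n_cells = nrow(grid), n_monitors = nrow(study$monitors),
      n_observations = nrow(study$observations),
      n_analysis_rows = nrow(tab_all),
      n_grid_predictions = nrow(pred_all)
    ),
    preprocess = prep$report,
    years = lapply(year_results, function(r) {
      r[c("year", "n_obs", "n_days", "bandwidth", "annual_mean")]
    }),
    change_region_mean = if (!is.null(change)) change$mean else NULL,
    warnings = warns,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  manifest$years_detail <- year_results
  manifest$time_series <- ts
  manifest$change <- change
  manifest$predictions <- pred_all
  invisible(manifest)
}

#' Read and validate pipeline input tables
#'
#' Reads the CSV schemas written by [write_study()] and validates them:
#' required columns present and of the right type, unique keys, legal
#' ranges.  Violations raise errors naming the offending columns and row
#' numbers.
#'
#' @param paths named list/vector with elements `monitors`, `observations`,
#'   `env`, `covariates` (file paths).
#' @return list of validated data.frames.
#' @export
read_inputs <- function(paths) {
  need <- c("monitors", "observations", "env", "covariates")
  stopifnot(all(need %in% names(paths)))
  out <- lapply(paths[need], function(p) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  validate_table(out$monitors, "monitors",
                 required = c(site_id = "character", x = "numeric",
                              y = "numeric"))
  validate_table(out$observations, "observations",
                 required = c(site_id = "character", date = "character",
                              pm25 = "numeric"),
                 key = c("site_id", "date"))
  validate_table(out$env, "env",
                 required = c(loc_id = "any", date = "character"),
                 key = c("loc_id", "date"))
  validate_table(out$covariates, "covariates",
                 required = c(x = "numeric", y = "numeric",
                              elevation = "numeric", forest_cover = "numeric",
                              road_length = "numeric",
                              point_emissions = "numeric"))
  fc <- out$covariates$forest_cover
  bad <- which(!is.na(fc) & (fc < 0 | fc > 1))
  if (length(bad) > 0) {
    stop("covariates: forest_cover outside [0,1] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  for (col in c("road_length", "point_emissions")) {
    v <- out$covariates[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop("covariates: negative ", col, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  out
}

validate_table <- function(df, name, required, key = NULL) {
  missing_cols <- setdiff(names(required), names(df))
  if (length(missing_cols) > 0) {
    stop(name, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in names(required)) {
    type <- required[[col]]
    if (type == "numeric" && !is.numeric(df[[col]])) {
      stop(name, ": column ", col, " must be numeric")
    }
    if (type == "character" && !is.character(df[[col]])) {
      stop(name, ": column ", col, " must be character")
    }
  }
  if (!is.null(key)) {
    k <- do.call(paste, df[key])
    dup <- which(duplicated(k))
    if (length(dup) > 0) {
      stop(name, ": duplicated (", paste(key, collapse = ", "),
           ") at row(s) ", paste(utils::head(dup, 5L), collapse = ", "))
    }
  }
  invisible(df)
}
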