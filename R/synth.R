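#' Configuration of a synthetic AOD--PM2.5 study
#'
#' Defines a square planar study domain on a regular 1 km grid with a sparse,
#' urban-biased monitor network, and all ground-truth parameters of the
#' generative model: day-level random effects with covariance `psi`, fixed
#' effects for AOD, relative humidity and four land-use covariates, a smooth
#' zero-mean spatially varying residual AOD slope `beta1(s)` (the stage-2
#' signal), a linear Terra--Aqua AOD relationship, and per-satellite
#' independent missingness.
#'
#' The default scale (50 x 50 km, 40 monitors, one year) keeps a full
#' pipeline run in minutes while preserving the structure of a large
#' regional study; all magnitudes (PM2.5 mean in the 11--16 ug/m3 band,
#' AOD mean ~0.2--0.3, meteorology and land-use ranges) follow typical
#' southeastern-US monitoring summaries.
#'
#' @param domain_size_km side of the square domain (km).
#' @param cell_size_km grid cell size (km); must divide `domain_size_km`.
#' @param n_monitors number of monitor sites (cells sampled without
#'   replacement).
#' @param n_days days simulated per year (<= 366).
#' @param n_years number of consecutive calendar years.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#' @param start_year first calendar year.
#' @param start_month first calendar month of each simulated year's window
#'   (1--12); days run consecutively from its first day.
#' @param urban_centers matrix of (x, y) urban-centre coordinates (km).
#' @param urban_bias monitor-placement bias: sampling weight is
#'   `1 + urban_bias * k(s)` with `k` the Gaussian urban kernel; 0 gives a
#'   spatially uniform network.
#' @param urban_range_km length-scale of the urban kernel (km).
#' @param fixed_effects named vector of true fixed effects: `intercept`
#'   (ug/m3), `aod` (ug/m3 per AOD unit), `rh` (ug/m3 per %RH), `elevation`
#'   (per m), `road_length` (per m), `forest_cover` (per unit fraction),
#'   `point_emissions` (per ton/yr).
#' @param psi true 3x3 symmetric PSD covariance of the day-level random
#'   (intercept, AOD slope, RH slope) vector.  Random slopes act on
#'   anomalies (covariate minus `random_centers`), so the day intercept is
#'   the day's deviation at typical conditions.
#' @param random_centers named reference values `c(aod=, rh=)` about which
#'   the day-level random slopes act.
#' @param residual_sd true residual standard deviation of the daily model
#'   (ug/m3).
#' @param monitor_noise_sd measurement noise of monitor observations (ug/m3).
#' @param beta1_sd marginal sd of the spatially varying residual AOD slope
#'   field (ug/m3 per AOD unit); 0 disables the stage-2 signal.
#' @param beta1_range_km length-scale of the `beta1` field (km).
#' @param terra_aqua_slope,terra_aqua_intercept linear map from the latent
#'   (Aqua) AOD to Terra AOD.
#' @param terra_noise_sd sd of the Terra measurement noise (AOD units).
#' @param missingness named probabilities `c(terra=, aqua=)` in `[0,1]` of a
#'   cell-day AOD value being missing, independently per satellite.
#' @param pm25_floor lower floor (ug/m3) applied to generated concentrations.
#' @return object of class `domain_config` (a validated list).
#' @export
domain_config <- function(domain_size_km = 50,
                          cell_size_km = 1,
                          n_monitors = 40L,
                          n_days = 365L,
                          n_years = 1L,
                          seed = 42L,
                          start_year = 2006L,
                          start_month = 1L,
                          urban_centers = matrix(c(25, 25), ncol = 2),
                          urban_bias = 8,
                          urban_range_km = 8,
                          fixed_effects = c(intercept = 12, aod = 15,
                                            rh = -0.05, elevation = -0.005,
                                            road_length = 0.005,
                                            forest_cover = -2,
                                            point_emissions = 0.02),
                          psi = matrix(c(4, 1, 0,
                                         1, 64, 0,
                                         0, 0, 2.25e-2), 3, 3),
                          random_centers = c(aod = 0.25, rh = 53),
                          residual_sd = 2.5,
                          monitor_noise_sd = 1,
                          beta1_sd = 5,
                          beta1_range_km = 15,
                          terra_aqua_slope = 0.9,
                          terra_aqua_intercept = 0.02,
                          terra_noise_sd = 0.02,
                          missingness = c(terra = 0.4, aqua = 0.5),
                          pm25_floor = 0.1) {
  cfg <- list(domain_size_km = domain_size_km, cell_size_km = cell_size_km,
              n_monitors = as.integer(n_monitors),
              n_days = as.integer(n_days), n_years = as.integer(n_years),
              seed = as.integer(seed), start_year = as.integer(start_year),
              start_month = as.integer(start_month),
              urban_centers = matrix(as.numeric(urban_centers), ncol = 2),
              urban_bias = urban_bias, urban_range_km = urban_range_km,
              fixed_effects = fixed_effects, psi = as.matrix(psi),
              random_centers = random_centers,
              residual_sd = residual_sd, monitor_noise_sd = monitor_noise_sd,
              beta1_sd = beta1_sd, beta1_range_km = beta1_range_km,
              terra_aqua_slope = terra_aqua_slope,
              terra_aqua_intercept = terra_aqua_intercept,
              terra_noise_sd = terra_noise_sd,
              missingness = missingness, pm25_floor = pm25_floor)
  validate_domain_config(cfg)
  structure(cfg, class = "domain_config")
}

validate_domain_config <- function(cfg) {
  stopifnot(cfg$domain_size_km > 0, cfg$cell_size_km > 0)
  n_side <- cfg$domain_size_km / cfg$cell_size_km
  if (abs(n_side - round(n_side)) > 1e-9) {
    stop("cell_size_km must divide domain_size_km")
  }
  stopifnot(cfg$n_monitors >= 1L, cfg$n_days >= 1L, cfg$n_days <= 366L,
            cfg$n_years >= 1L)
  fe_names <- c("intercept", "aod", "rh", "elevation", "road_length",
                "forest_cover", "point_emissions")
  if (!all(fe_names %in% names(cfg$fixed_effects))) {
    stop("fixed_effects must be named: ", paste(fe_names, collapse = ", "))
  }
  psi <- cfg$psi
  if (nrow(psi) != 3L || ncol(psi) != 3L ||
      max(abs(psi - t(psi))) > 1e-8) {
    stop("psi must be a symmetric 3 x 3 matrix")
  }
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("psi must be positive semi-definite")
  }
  miss <- cfg$missingness
  if (!all(c("terra", "aqua") %in% names(miss)) ||
      any(miss < 0) || any(miss > 1)) {
    stop("missingness must be named probabilities c(terra=, aqua=) in [0,1]")
  }
  stopifnot(cfg$residual_sd >= 0, cfg$monitor_noise_sd >= 0,
            cfg$beta1_sd >= 0, cfg$pm25_floor > 0)
  invisible(cfg)
}

# Calendar days of the study: n_days from start_month's first day in each
# simulated year.
study_dates <- function(config) {
  sm <- if (is.null(config$start_month)) 1L else config$start_month
  unlist(lapply(seq_len(config$n_years) - 1L, function(y) {
    start <- as.Date(sprintf("%d-%02d-01", config$start_year + y, sm))
    as.character(seq(start, by = "day", length.out = config$n_days))
  }))
}

#' Generate the study domain: grid and monitor network
#'
#' Lays out a regular square grid of cell centres (row-major in x, then y)
#' and samples monitor cells without replacement with probability weight
#' `1 + urban_bias * k(s)`, emulating the urban bias of real ground
#' networks.  Deterministic given `config$seed`.
#'
#' @param config a [domain_config()].
#' @return object of class `synth_study` with `grid` and `monitors` filled.
#' @export
generate_domain <- function(config) {
  validate_domain_config(config)
  n_side <- as.integer(round(config$domain_size_km / config$cell_size_km))
  centers <- (seq_len(n_side) - 0.5) * config$cell_size_km
  grid <- expand.grid(x = centers, y = centers, KEEP.OUT.ATTRS = FALSE)
  grid <- data.frame(cell_id = seq_len(nrow(grid)), x = grid$x, y = grid$y)
  if (config$n_monitors > nrow(grid)) {
    stop("n_monitors (", config$n_monitors, ") exceeds the number of grid ",
         "cells (", nrow(grid), ")")
  }
  set.seed(config$seed)
  uk <- urban_kernel(grid[, c("x", "y")], config$urban_centers,
                     config$urban_range_km)
  w <- 1 + config$urban_bias * uk
  idx <- sample.int(nrow(grid), config$n_monitors, prob = w)
  monitors <- data.frame(
    site_id = sprintf("S%03d", seq_len(config$n_monitors)),
    cell_id = grid$cell_id[idx],
    x = grid$x[idx], y = grid$y[idx]
  )
  structure(
    list(config = config, grid = grid, monitors = monitors,
         env = NULL, observations = NULL, truth = list()),
    class = "synth_study"
  )
}

#' Simulate static land-use covariates
#'
#' Fills the grid (and, by cell membership, the monitors) with elevation
#' (smooth Gaussian random field, floored), forest cover (logistic transform
#' of a smooth field, depressed near urban centres, in `[0, 1]`), highway
#' road length (zero off a few straight corridors, plus urban arterials) and
#' point-source emissions (zero-inflated, log-normal magnitudes, more
#' frequent near urban centres).
#'
#' @param study a `synth_study` from [generate_domain()].
#' @param config the study's [domain_config()]; defaults to `study$config`.
#' @return the study with covariate columns added to `grid` and `monitors`.
#' @export
simulate_covariates <- function(study, config = study$config) {
  stopifnot(inherits(study, "synth_study"), !is.null(study$grid))
  set.seed(config$seed + 1L)
  grid <- study$grid
  xy <- as.matrix(grid[, c("x", "y")])
  n <- nrow(grid)
  uk <- urban_kernel(xy, config$urban_centers, config$urban_range_km)

  grid$elevation <- pmax(230 + sim_grf(xy, range_km = 12, sd = 120), 40)
  grid$forest_cover <- stats::plogis(
    -1.6 + 1.2 * sim_grf(xy, range_km = 10, sd = 1) - 2.5 * uk
  )

  # Highway corridors: straight chords through the neighbourhood of the
  # first urban centre; cells within half a cell of a corridor get road
  # length, everything else is exactly zero.
  road <- numeric(n)
  n_corridors <- 3L
  for (i in seq_len(n_corridors)) {
    p <- config$urban_centers[1L, ] + stats::rnorm(2L, sd = 4)
    theta <- stats::runif(1L, 0, pi)
    normal <- c(-sin(theta), cos(theta))
    d <- abs((xy[, 1L] - p[1L]) * normal[1L] + (xy[, 2L] - p[2L]) * normal[2L])
    on_corridor <- d < 0.7 * config$cell_size_km
    road[on_corridor] <- road[on_corridor] +
      pmax(stats::rnorm(sum(on_corridor), 800, 150), 0)
  }
  arterial <- uk > 0.5 & stats::runif(n) < 0.3
  road[arterial] <- road[arterial] + pmax(stats::rnorm(sum(arterial), 400, 100), 0)
  grid$road_length <- road

  # facilities cluster in urban areas and along highway corridors
  src <- stats::runif(n) < (0.02 + 0.2 * uk + 0.3 * (road > 0))
  emis <- numeric(n)
  emis[src] <- stats::rlnorm(sum(src), meanlog = log(120), sdlog = 1)
  grid$point_emissions <- emis

  study$grid <- grid
  cov_cols <- c("elevation", "forest_cover", "road_length", "point_emissions")
  study$monitors[cov_cols] <-
    grid[match(study$monitors$cell_id, grid$cell_id), cov_cols]
  study$truth$urban_kernel <- uk
  study
}

#' Simulate daily AOD and meteorology
#'
#' Generates a latent nonnegative daily AOD field (log-scale seasonal cycle
#' peaking in summer, AR(1) day effects, spatially and temporally
#' autocorrelated smooth fields, urban excess).  Aqua AOD equals the latent
#' field; Terra AOD is `intercept + slope * latent + noise`, floored at 0.
#' Each satellite's values are then masked independently at its missingness
#' rate.  Meteorology (relative humidity, boundary-layer height, wind
#' components; wind speed derived) is generated as smooth space-time fields
#' within realistic regional ranges.
#'
#' @inheritParams simulate_covariates
#' @return the study with `env` (long cell-day data.frame) and latent truth
#'   fields filled.
#' @export
simulate_env <- function(study, config = study$config) {
  stopifnot(inherits(study, "synth_study"), !is.null(study$grid))
  set.seed(config$seed + 2L)
  grid <- study$grid
  xy <- as.matrix(grid[, c("x", "y")])
  n <- nrow(grid)
  dates <- study_dates(config)
  nt <- length(dates)
  doy <- as.integer(format(as.Date(dates), "%j"))

  uk <- study$truth$urban_kernel
  if (is.null(uk)) uk <- urban_kernel(xy, config$urban_centers,
                                      config$urban_range_km)

  # log-scale latent AOD: seasonal + AR(1) day + space-time field + urban
  season <- 0.25 * cos(2 * pi * (doy - 212) / 365.25)
  day_ar <- numeric(nt)
  day_ar[1L] <- stats::rnorm(1L, sd = 0.3)
  if (nt > 1L) for (t in 2L:nt) {
    day_ar[t] <- 0.6 * day_ar[t - 1L] + sqrt(1 - 0.36) * stats::rnorm(1L, sd = 0.3)
  }
  spat <- sim_daily_field(xy, nt, range_km = 10, sd = 0.5, ar1 = 0.5)
  log_aod <- sweep(spat, 2L, log(0.22) + season + day_ar, "+") + 0.2 * uk
  aod_latent <- exp(log_aod)                       # n x nt, > 0

  terra_true <- pmax(config$terra_aqua_intercept +
                       config$terra_aqua_slope * aod_latent +
                       matrix(stats::rnorm(n * nt, sd = config$terra_noise_sd),
                              n, nt), 0)
  aqua <- aod_latent
  terra <- terra_true
  terra[matrix(stats::runif(n * nt) < config$missingness[["terra"]], n, nt)] <- NA_real_
  aqua[matrix(stats::runif(n * nt) < config$missingness[["aqua"]], n, nt)] <- NA_real_

  rh <- pmin(pmax(53 + sim_daily_field(xy, nt, range_km = 25, sd = 9, ar1 = 0.7),
                  5), 100)
  blh <- pmax(1300 + sim_daily_field(xy, nt, range_km = 30, sd = 380, ar1 = 0.6),
              150)
  u_wind <- 1.1 + sim_daily_field(xy, nt, range_km = 30, sd = 2.8, ar1 = 0.5)
  v_wind <- -0.4 + sim_daily_field(xy, nt, range_km = 30, sd = 2.7, ar1 = 0.5)
  wind_speed <- sqrt(u_wind^2 + v_wind^2)

  env <- data.frame(
    loc_id = rep(grid$cell_id, times = nt),
    date = rep(dates, each = n),
    aod_terra = as.vector(terra),
    aod_aqua = as.vector(aqua),
    rh = as.vector(rh),
    blh = as.vector(blh),
    u_wind = as.vector(u_wind),
    v_wind = as.vector(v_wind),
    wind_speed = as.vector(wind_speed),
    stringsAsFactors = FALSE
  )
  study$env <- env
  study$truth$dates <- dates
  study$truth$aod_latent <- `dimnames<-`(aod_latent, list(grid$cell_id, dates))
  study$truth$rh <- `dimnames<-`(rh, list(grid$cell_id, dates))
  study
}

#' Simulate PM2.5 truth surfaces and monitor observations
#'
#' For each day draws a random (intercept, AOD slope, RH slope) vector from
#' `N(0, psi)`, adds the smooth zero-mean spatial slope field `beta1(s)`,
#' and composes the noiseless concentration surface
#' `(b0 + b0t) + (b1 + beta1(s)) AOD + b1t (AOD - AOD_ref) + b2 RH +
#'  b2t (RH - RH_ref) + b3 elev + b4 roads + b5 forest + b6 emissions`
#' on the latent (unmasked) AOD; the day-level random slopes act on
#' anomalies about `random_centers`.  Monitor observations are the truth at
#' monitor cells plus the daily residual and independent measurement noise;
#' all concentrations are floored at `pm25_floor`.
#'
#' @inheritParams simulate_covariates
#' @return the study with `observations` and truth components
#'   (`day_effects`, `beta1`, `pm25_true`) filled.
#' @export
simulate_pm25 <- function(study, config = study$config) {
  stopifnot(inherits(study, "synth_study"))
  if (is.null(study$env)) stop("simulate_env() must be run before simulate_pm25()")
  if (is.null(study$grid$elevation)) {
    stop("simulate_covariates() must be run before simulate_pm25()")
  }
  set.seed(config$seed + 3L)
  grid <- study$grid
  dates <- study$truth$dates
  nt <- length(dates)
  n <- nrow(grid)
  fe <- config$fixed_effects

  re <- matrix(stats::rnorm(nt * 3L), nt, 3L) %*% psd_sqrt(config$psi)
  colnames(re) <- c("b0t", "b1t", "b2t")
  day_effects <- data.frame(date = dates, re, stringsAsFactors = FALSE)

  beta1 <- if (config$beta1_sd > 0) {
    sim_grf(as.matrix(grid[, c("x", "y")]), range_km = config$beta1_range_km,
            sd = config$beta1_sd)
  } else {
    numeric(n)
  }

  aod <- study$truth$aod_latent
  rh <- study$truth$rh
  static <- fe[["intercept"]] +
    fe[["elevation"]] * grid$elevation +
    fe[["road_length"]] * grid$road_length +
    fe[["forest_cover"]] * grid$forest_cover +
    fe[["point_emissions"]] * grid$point_emissions

  slope <- fe[["aod"]] + beta1                                  # n-vector
  ctr <- config$random_centers
  pm <- static +
    aod * slope +                                               # recycle by col
    sweep(aod - ctr[["aod"]], 2L, re[, "b1t"], "*") +
    rh * fe[["rh"]] + sweep(rh - ctr[["rh"]], 2L, re[, "b2t"], "*")
  pm <- sweep(pm, 2L, re[, "b0t"], "+")
  pm_true <- pmax(pm, config$pm25_floor)
  dimnames(pm_true) <- list(grid$cell_id, dates)

  mcells <- match(study$monitors$cell_id, grid$cell_id)
  nm <- length(mcells)
  noise <- matrix(stats::rnorm(nm * nt, sd = config$residual_sd), nm, nt) +
    matrix(stats::rnorm(nm * nt, sd = config$monitor_noise_sd), nm, nt)
  obs <- pmax(pm_true[mcells, , drop = FALSE] + noise, config$pm25_floor)
  observations <- data.frame(
    site_id = rep(study$monitors$site_id, times = nt),
    date = rep(dates, each = nm),
    pm25 = as.vector(obs),
    stringsAsFactors = FALSE
  )

  study$observations <- observations
  study$truth$day_effects <- day_effects
  study$truth$beta1 <- stats::setNames(beta1, grid$cell_id)
  study$truth$pm25_true <- pm_true
  study
}

#' Generate a complete synthetic study
#'
#' Runs [generate_domain()], [simulate_covariates()], [simulate_env()] and
#' [simulate_pm25()] in sequence.  Bit-reproducible given the config.
#'
#' @param config a [domain_config()].
#' @return a fully populated `synth_study`.
#' @export
synth_study <- function(config = domain_config()) {
  study <- generate_domain(config)
  study <- simulate_covariates(study, config)
  study <- simulate_env(study, config)
  simulate_pm25(study, config)
}

#' @export
print.synth_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic AOD-PM2.5 study\n")
  cat(sprintf("  domain: %g x %g km, %d cells of %g km\n",
              cfg$domain_size_km, cfg$domain_size_km,
              nrow(x$grid), cfg$cell_size_km))
  cat(sprintf("  monitors: %d, days: %d x %d year(s), seed: %d\n",
              nrow(x$monitors), cfg$n_days, cfg$n_years, cfg$seed))
  if (!is.null(x$observations)) {
    cat(sprintf("  observations: %d site-days, mean PM2.5 %.2f ug/m3\n",
                nrow(x$observations), mean(x$observations$pm25)))
  }
  invisible(x)
}

#' Write or read a synthetic study as plain CSV tables
#'
#' `write_study()` writes `monitors.csv`, `observations.csv`,
#' `env_daily.csv` and `covariates.csv` (grid cells with coordinates and
#' land-use covariates), plus a `truth.json` sidecar holding the generative
#' parameters, the per-day random-effect draws and the `beta1(s)` field.
#' `read_study()` reads the four tables back.
#'
#' @param study a `synth_study`.
#' @param dir output directory (created if absent).
#' @return `write_study()` returns the directory invisibly; `read_study()`
#'   returns a list of the four data.frames.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$monitors, file.path(dir, "monitors.csv"),
                   row.names = FALSE)
  utils::write.csv(study$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$env, file.path(dir, "env_daily.csv"),
                   row.names = FALSE)
  cov_cols <- c("cell_id", "x", "y", "elevation", "forest_cover",
                "road_length", "point_emissions")
  utils::write.csv(study$grid[, cov_cols], file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  cfg <- study$config
  truth <- list(
    fixed_effects = as.list(cfg$fixed_effects),
    psi = unclass(cfg$psi),
    residual_sd = cfg$residual_sd,
    monitor_noise_sd = cfg$monitor_noise_sd,
    terra_aqua = c(intercept = cfg$terra_aqua_intercept,
                   slope = cfg$terra_aqua_slope),
    day_effects = study$truth$day_effects,
    beta1 = as.list(study$truth$beta1)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  read1 <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing study file: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(monitors = read1("monitors.csv"),
       observations = read1("observations.csv"),
       env = read1("env_daily.csv"),
       covariates = read1("covariates.csv"))
}
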