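test_that("detection-limit filter drops strictly sub-limit records", {
  rec <- data.frame(site_id = "a", date = "2006-01-01",
                    pm25 = c(1.9, 2.0, 11.0))
  out <- filter_pm25(rec)
  expect_equal(out$pm25, c(2.0, 11.0))                 # strict less-than
  expect_equal(attr(out, "removed_fraction"), 1 / 3)

  empty <- filter_pm25(rec[0, ])
  expect_equal(nrow(empty), 0)

  high <- data.frame(pm25 = c(2, 5, 50))
  expect_equal(filter_pm25(high)$pm25, high$pm25)      # no-op case
  expect_equal(attr(filter_pm25(high), "removed_fraction"), 0)
})

test_that("satellite link regression recovers a synthetic linkage", {
  set.seed(17)
  n_days <- 60; n_loc <- 25
  dates <- as.character(seq(as.Date("2006-01-01"), by = "day",
                            length.out = n_days))
  aqua <- matrix(runif(n_loc * n_days, 0.05, 0.8), n_loc, n_days)
  terra <- 0.02 + 0.9 * aqua + matrix(rnorm(n_loc * n_days, sd = 0.01),
                                      n_loc, n_days)
  env <- data.frame(loc_id = rep(1:n_loc, n_days),
                    date = rep(dates, each = n_loc),
                    aod_terra = as.vector(terra), aod_aqua = as.vector(aqua))
  link <- fit_satellite_link(env)
  l <- link[["2006"]]
  # oracle: the same daily-mean regression fitted directly
  tm <- colMeans(terra); am <- colMeans(aqua)
  oracle <- lm(tm ~ am)
  se <- coef(summary(oracle))[, "Std. Error"]
  expect_lt(abs(l$terra_on_aqua[["slope"]] - 0.9), 2 * se[2])
  expect_lt(abs(l$terra_on_aqua[["intercept"]] - 0.02), 2 * se[1])
  expect_equal(unname(l$terra_on_aqua), unname(coef(oracle)))

  # identity data: slope 1, intercept 0 to machine precision
  env_id <- env; env_id$aod_terra <- env_id$aod_aqua
  lid <- fit_satellite_link(env_id)[["2006"]]
  expect_equal(lid$terra_on_aqua[["slope"]], 1, tolerance = 1e-12)
  expect_equal(lid$terra_on_aqua[["intercept"]], 0, tolerance = 1e-12)

  # degenerate: constant Aqua series
  env_c <- env; env_c$aod_aqua <- 0.3
  expect_error(fit_satellite_link(env_c), "degenerate")

  # insufficient days names the year
  expect_error(fit_satellite_link(env[env$date <= dates[5], ]), "2006")
})

test_that("AOD combination averages, cross-imputes and caps at 2.0", {
  link <- structure(list(
    "2006" = list(terra_on_aqua = c(intercept = 0, slope = 1),
                  aqua_on_terra = c(intercept = 0, slope = 1), n_days = 30)
  ), class = "satellite_link")
  env <- data.frame(
    loc_id = 1:5, date = "2006-07-01",
    aod_terra = c(0.2, NA, 0.5, NA, 2.6),
    aod_aqua  = c(0.4, 0.3, NA, NA, 2.2))
  out <- combine_aod(env, link)
  expect_equal(out$aod_combined[1], 0.3)               # both: average
  expect_equal(out$aod_combined[2], 0.3)               # identity link: (0.3+0.3)/2
  expect_equal(out$aod_combined[3], 0.5)
  expect_true(is.na(out$aod_combined[4]))              # neither
  expect_true(is.na(out$aod_combined[5]))              # 2.4 > 2.0 excluded
  expect_equal(attr(out, "excluded_fraction"), 1 / 4)

  # with a non-trivial link, one-satellite rows use the cross-prediction
  link2 <- structure(list(
    "2006" = list(terra_on_aqua = c(intercept = 0.02, slope = 0.9),
                  aqua_on_terra = c(intercept = -0.02 / 0.9, slope = 1 / 0.9),
                  n_days = 30)
  ), class = "satellite_link")
  env2 <- data.frame(loc_id = 1, date = "2006-07-01",
                     aod_terra = NA_real_, aod_aqua = 0.3)
  out2 <- combine_aod(env2, link2)
  expect_equal(out2$aod_combined, (0.3 + (0.02 + 0.9 * 0.3)) / 2)

  # inverse-link symmetry: swapping satellite labels gives the same value
  env3 <- data.frame(loc_id = 1, date = "2006-07-01",
                     aod_terra = 0.29, aod_aqua = NA_real_)
  out3 <- combine_aod(env3, link2)
  expect_equal(out3$aod_combined, (0.29 + (0.29 - 0.02) / 0.9) / 2)

  expect_error(combine_aod(data.frame(loc_id = 1, date = "2011-01-01",
                                      aod_terra = 1, aod_aqua = 1), link),
               "2011")
})

test_that("daytime meteorology averaging uses the closed 10:00-16:00 window", {
  h <- expand.grid(loc_id = 1L, date = "2006-07-01", hour = 1:24)
  h$temp <- h$hour                       # value h at hour h
  out <- average_daytime_met(h)
  expect_equal(out$temp, mean(10:16))    # = 13

  h$temp <- 7.5                          # constant series
  expect_equal(average_daytime_met(h)$temp, 7.5)

  h3 <- data.frame(loc_id = 1L, date = "2006-07-01", hour = c(10, 13, 16),
                   temp = c(2, 4, 6))    # 3-hourly
  expect_equal(average_daytime_met(h3)$temp, 4)

  # day with no timestamps in the window is missing, not dropped
  hn <- data.frame(loc_id = 1L, date = c("2006-07-01", "2006-07-02"),
                   hour = c(12, 20), temp = c(5, 9))
  out <- average_daytime_met(hn)
  expect_equal(nrow(out), 2)
  expect_equal(out$temp[out$date == "2006-07-01"], 5)
  expect_true(is.na(out$temp[out$date == "2006-07-02"]))
})

test_that("buffer aggregation averages terrain and sums roads/emissions", {
  raw <- data.frame(
    x = c(0.1, -0.2, 0.3, 2.0),          # last sample is outside the buffer
    y = c(0.0, 0.1, -0.3, 0.0),
    elevation = c(100, 200, 150, 999),
    forest_cover = c(0.2, 0.4, 0.6, 1.0),
    road_length = c(300, 200, 0, 5000),
    point_emissions = c(0, 0, 0, 77))
  out <- aggregate_buffer(raw, c(0, 0))
  expect_equal(out$elevation, 150)
  expect_equal(out$forest_cover, 0.4)
  expect_equal(out$road_length, 500)
  expect_equal(out$point_emissions, 0)   # no sources in buffer -> 0

  two <- aggregate_buffer(data.frame(x = c(0, 0.2), y = c(0, 0),
                                     elevation = c(100, 200)), c(0, 0))
  expect_equal(two$elevation, 150)

  expect_error(aggregate_buffer(raw, c(50, 50)), "no elevation")
})

test_that("nearest-neighbour assignment is deterministic and never falls back", {
  field <- data.frame(loc_id = c(2L, 1L, 3L), x = c(0, 1, 5), y = c(0, 0, 0),
                      value = c(10, 20, 30))
  expect_equal(assign_nearest(field, c(0, 0)), 10)     # coincident node
  # equidistant between nodes 2 (x=0) and 1 (x=1): lowest id wins
  expect_equal(assign_nearest(field, c(0.5, 0)), 20)
  # nearest node missing that day: result missing, no fallback
  field$value[1] <- NA
  expect_true(is.na(assign_nearest(field, c(0, 0))))
})

test_that("analysis table join drops missing predictors with accounting", {
  obs <- data.frame(site_id = rep(c("a", "b"), each = 2),
                    date = rep(c("2006-07-01", "2006-07-02"), 2),
                    pm25 = c(10, 12, 14, 16))
  env <- data.frame(loc_id = rep(c("a", "b"), each = 2),
                    date = rep(c("2006-07-01", "2006-07-02"), 2),
                    aod_combined = c(0.3, NA, 0.5, 0.4),
                    rh = c(50, 55, 60, 65))
  cov <- data.frame(site_id = c("a", "b"), x = 1:2, y = 1:2,
                    elevation = c(100, 200), forest_cover = c(0.1, 0.2),
                    road_length = c(0, 500), point_emissions = c(0, 3))
  tab <- build_analysis_table(obs, env, cov)
  expect_equal(nrow(tab), 3)                   # the missing-AOD row is gone
  expect_false(any(tab$site_id == "a" & tab$date == "2006-07-02"))
  rep <- attr(tab, "report")
  expect_equal(rep$dropped_missing_aod, 1)
  expect_equal(rep$n_retained, 3)
  expect_true(!anyNA(tab))

  # duplicated key is rejected
  expect_error(build_analysis_table(rbind(obs, obs[1, ]), env, cov),
               "duplicated")
  # empty result errors
  env_na <- env; env_na$aod_combined <- NA_real_
  expect_error(build_analysis_table(obs, env_na, cov), "empty")
})

test_that("full preparation retains monitors x days when nothing is missing", {
  cfg <- domain_config(domain_size_km = 12, n_monitors = 8, n_days = 30,
                       missingness = c(terra = 0, aqua = 0),
                       residual_sd = 0.5, monitor_noise_sd = 0.2, seed = 6)
  st <- synth_study(cfg)
  prep <- prepare_study(st)
  n_filtered <- nrow(filter_pm25(st$observations))
  expect_equal(nrow(prep$table), n_filtered)   # nothing else drops
  expect_equal(n_filtered, 8 * 30)             # no sub-limit values here
  # row counts are non-increasing through the chain and fully attributed
  r <- prep$report
  expect_equal(r$n_joined - r$dropped_missing_aod - r$dropped_missing_met -
                 r$dropped_missing_covariate, r$n_retained)
})
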