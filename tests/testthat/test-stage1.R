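test_that("zero Psi degenerates to pooled OLS with shrunken day effects", {
  cfg <- domain_config(domain_size_km = 15, n_monitors = 25, n_days = 40,
                       psi = matrix(0, 3, 3), beta1_sd = 0, seed = 9)
  st <- synth_study(cfg)
  tab <- prepare_study(st)$table
  spec <- true_spec()
  fit <- suppressWarnings(fit_stage1(tab, spec))
  # day effects shrink toward zero on average
  expect_lt(max(abs(colMeans(as.matrix(fit$random[, -1])))), 0.25)
  # the estimated day-intercept variance collapses
  expect_lt(fit$psi[1, 1], 1)
  # the fixed-effect surface matches pooled OLS closely
  ols <- lm(reformulate(spec$fixed, "pm25"), data = tab)
  X <- model.matrix(reformulate(spec$fixed), tab)
  expect_lt(mean(abs(X %*% fit$fixed - X %*% coef(ols))), 0.1)
  # Psi estimate is (numerically) PSD
  ev <- eigen(fit$psi, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("a single day of data reduces to OLS with pinned day effect", {
  tab <- summer_study()$table
  one <- tab[tab$date == tab$date[1], ]
  expect_message(fit <- fit_stage1(one, true_spec()), "single day")
  expect_true(fit$single_day)
  expect_equal(as.numeric(as.matrix(fit$random[, -1])), rep(0, 3))
  ols <- lm(reformulate(true_spec()$fixed, "pm25"), data = one)
  expect_equal(unname(fit$fixed), unname(coef(ols)))
})

test_that("stage-1 fit recovers structure and predicts self-consistently", {
  fx <- summer_study()
  tab <- fx$table
  spec <- true_spec()
  fit <- suppressWarnings(fit_stage1(tab, spec))

  expect_equal(nrow(fit$random), length(unique(tab$date)))
  # BLUP means are shrinkage-centred near zero
  expect_lt(max(abs(colMeans(as.matrix(fit$random[, -1])))), 0.5)
  expect_true(all(eigen(fit$psi, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_gt(fit$sigma2, 0)

  # residual identity at monitor rows
  rdf <- stage1_residuals(fit, tab)
  expect_equal(rdf$pred1 + rdf$resid, tab$pm25)

  # unseen date: fixed-effects-only prediction, flagged
  nd <- tab[1:4, ]
  nd$date <- "2030-01-01"
  p <- predict_stage1(fit, nd)
  expect_true(all(attr(p, "fixed_only")))
  X <- model.matrix(reformulate(spec$fixed), nd)
  expect_equal(as.numeric(p), unname(drop(X %*% fit$fixed[colnames(X)])))

  # prediction is linear in AOD with day slope exactly b1 + b1t
  nd2 <- tab[5:8, ]
  p0 <- as.numeric(predict_stage1(fit, nd2))
  nd2$aod <- nd2$aod + 1
  p1 <- as.numeric(predict_stage1(fit, nd2))
  b1t <- fit$random$aod[match(nd2$date, fit$random$date)]
  expect_equal(p1 - p0, unname(fit$fixed[["aod"]] + b1t))

  expect_error(predict_stage1(fit, nd2[, setdiff(names(nd2), "rh")]),
               "rh")
})

test_that("grid predictions track the noiseless truth surfaces", {
  fx <- summer_study()
  st <- fx$study
  fit <- suppressWarnings(fit_stage1(fx$table, true_spec()))
  # predict every cell-day using the latent truth env (all days seen)
  days <- st$truth$dates
  n <- nrow(st$grid)
  nd <- data.frame(
    date = rep(days, each = n),
    aod = as.vector(st$truth$aod_latent),
    rh = as.vector(st$truth$rh),
    elevation = rep(st$grid$elevation, times = length(days)),
    road_length = rep(st$grid$road_length, times = length(days)),
    forest_cover = rep(st$grid$forest_cover, times = length(days)),
    point_emissions = rep(st$grid$point_emissions, times = length(days)))
  p <- as.numeric(predict_stage1(fit, nd))
  truth <- as.vector(st$truth$pm25_true)
  expect_gt(cor(p, truth)^2, 0.8)
})

test_that("variance components match a method-of-moments oracle", {
  # balanced one-way random-intercept design
  set.seed(33)
  n_day <- 60; n_per <- 12
  mu <- 10; tau2 <- 4; s2 <- 2.25
  a <- rnorm(n_day, sd = sqrt(tau2))
  y <- mu + rep(a, each = n_per) + rnorm(n_day * n_per, sd = sqrt(s2))
  dates <- rep(sprintf("2006-06-%02d", seq_len(n_day)), each = n_per)
  tab <- data.frame(site_id = "s", date = dates, pm25 = y, aod = 1)

  # method-of-moments oracle from the one-way ANOVA decomposition
  ybar <- tapply(y, dates, mean)
  ms_within <- sum((y - ybar[dates])^2) / (n_day * (n_per - 1))
  ms_between <- n_per * sum((ybar - mean(y))^2) / (n_day - 1)
  mom_s2 <- ms_within
  mom_tau2 <- (ms_between - ms_within) / n_per

  spec <- stage1_spec(fixed = "aod", random = character(0))
  fit <- suppressMessages(suppressWarnings(fit_stage1(tab, spec)))
  expect_equal(fit$sigma2, mom_s2, tolerance = 0.05)
  expect_equal(unname(fit$psi[1, 1]), mom_tau2, tolerance = 0.1 * tau2 + 0.05)
})

test_that("backward elimination drops null terms and protects AOD", {
  # forest-cover effect set to zero: elimination should remove it reliably
  n_rep <- 8; eliminated_forest <- 0
  fe <- c(intercept = 12, aod = 15, rh = -0.1, elevation = -0.005,
          road_length = 0.005, forest_cover = 0, point_emissions = 0.02)
  for (r in seq_len(n_rep)) {
    cfg <- domain_config(domain_size_km = 25, n_monitors = 30, n_days = 60,
                         start_month = 6L, fixed_effects = fe, beta1_sd = 0,
                         seed = 200 + r)
    tab <- prepare_study(synth_study(cfg))$table
    red <- select_variables(tab, true_spec())
    if (!"forest_cover" %in% red$fixed) eliminated_forest <- eliminated_forest + 1
    expect_true("aod" %in% red$fixed)            # protected term
  }
  expect_gte(eliminated_forest, 6)

  # strong signal throughout: the full specification is retained
  cfg <- domain_config(domain_size_km = 25, n_monitors = 30, n_days = 90,
                       start_month = 6L,
                       fixed_effects = c(intercept = 12, aod = 15, rh = -0.1,
                                         elevation = -0.01, road_length = 0.005,
                                         forest_cover = -4,
                                         point_emissions = 0.02),
                       beta1_sd = 0, seed = 55)
  tab <- prepare_study(synth_study(cfg))$table
  red <- select_variables(tab, true_spec())
  expect_setequal(red$fixed, true_spec()$fixed)

  # AOD is retained even when its true coefficient is zero
  fe0 <- fe; fe0[["aod"]] <- 0; fe0[["forest_cover"]] <- -4
  cfg0 <- domain_config(domain_size_km = 25, n_monitors = 30, n_days = 60,
                        start_month = 6L, fixed_effects = fe0, beta1_sd = 0,
                        psi = diag(c(4, 1e-6, 2.25e-2)), seed = 77)
  tab0 <- prepare_study(synth_study(cfg0))$table
  red0 <- select_variables(tab0, true_spec())
  expect_true("aod" %in% red0$fixed)
})
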