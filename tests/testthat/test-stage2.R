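make_month <- function(n = 150, seed = 41) {
  set.seed(seed)
  data.frame(
    site_id = rep(sprintf("S%02d", 1:30), length.out = n),
    month = "2006-07",
    x = runif(n, 0, 40), y = runif(n, 0, 40),
    aod = runif(n, 0.05, 0.9),
    resid = rnorm(n, sd = 2))
}

test_that("kernel weights are proper and monotone", {
  d <- seq(0, 30, by = 0.5)
  for (k in c("gaussian", "bisquare")) {
    w <- kernel_weights(d, 10, k)
    expect_equal(w[1], 1)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(diff(w) <= 1e-12))       # non-increasing
  }
  expect_equal(kernel_weights(d, Inf), rep(1, length(d)))
  expect_equal(kernel_weights(15, 10, "bisquare"), 0)  # outside support
})

test_that("GWR coefficients match a dense weighted-least-squares oracle", {
  dat <- make_month()
  targets <- data.frame(loc_id = 1:20,
                        x = runif(20, 0, 40), y = runif(20, 0, 40))
  for (bw in c(3, 8, 25)) {
    got <- fit_gwr_month(dat, targets, gwr_spec(), bandwidth = bw)
    for (i in seq_len(nrow(targets))) {
      d <- sqrt((dat$x - targets$x[i])^2 + (dat$y - targets$y[i])^2)
      w <- exp(-d^2 / (2 * bw^2))
      oracle <- lm.wfit(cbind(1, dat$aod), dat$resid, w)$coefficients
      expect_lt(abs(got$beta0[i] - oracle[1]) / max(abs(oracle[1]), 1e-8),
                1e-8)
      expect_lt(abs(got$beta1[i] - oracle[2]) / max(abs(oracle[2]), 1e-8),
                1e-8)
    }
  }
})

test_that("infinite bandwidth reproduces global OLS everywhere", {
  dat <- make_month(seed = 43)
  targets <- data.frame(loc_id = 1:10, x = runif(10, 0, 40),
                        y = runif(10, 0, 40))
  got <- fit_gwr_month(dat, targets, gwr_spec(), bandwidth = Inf)
  ols <- coef(lm(resid ~ aod, data = dat))
  expect_equal(got$beta0, rep(unname(ols[1]), 10), tolerance = 1e-12)
  expect_equal(got$beta1, rep(unname(ols[2]), 10), tolerance = 1e-12)
})

test_that("degenerate local designs are flagged with mean-residual fallback", {
  dat <- make_month(seed = 44)
  dat$aod <- 0.4                              # constant AOD
  targets <- data.frame(loc_id = 1, x = 20, y = 20)
  expect_warning(got <- fit_gwr_month(dat, targets, gwr_spec(),
                                      bandwidth = 10),
                 "rank-deficient")
  expect_true(got$flagged[1])
  expect_equal(got$beta1[1], 0)
  d <- sqrt((dat$x - 20)^2 + (dat$y - 20)^2)
  w <- exp(-d^2 / 200)
  expect_equal(got$beta0[1], sum(w * dat$resid) / sum(w))

  expect_error(fit_gwr_month(dat[1:5, ], targets, gwr_spec(), bandwidth = 5),
               "need >=")
})

test_that("bandwidth selection reacts to the spatial scale of the signal", {
  # spatially constant residual process: wide kernels dominate (the CV
  # profile decreases toward large bandwidths and the pick is in the
  # widest part of the grid)
  set.seed(51)
  dat <- make_month(300, seed = 51)
  dat$resid <- 0.8 + 2.5 * dat$aod + rnorm(300, sd = 0.3)
  cand <- c(2, 5, 10, 20, 40)
  bw <- suppressWarnings(select_bandwidth(dat, gwr_spec(),
                                          candidates = cand))
  expect_gte(as.numeric(bw), 20)
  prof <- attr(bw, "profile")
  expect_equal(nrow(prof), 5)
  expect_gt(prof$cv_rmse[1], prof$cv_rmse[5])

  # single candidate: returned unchanged
  expect_equal(select_bandwidth(dat, gwr_spec(), candidates = 7), 7)

  # strong short-range slope variation: selected bandwidth well below the
  # domain scale
  fx <- summer_study()
  fit <- suppressWarnings(fit_stage1(fx$table, true_spec()))
  rdf <- stage1_residuals(fit, fx$table)
  bw2 <- suppressWarnings(select_bandwidth(rdf, gwr_spec()))
  expect_lt(as.numeric(bw2), 30 / 2)          # domain is 30 km

  # a two-candidate grid is minimised at an edge by construction
  expect_warning(select_bandwidth(rdf, gwr_spec(), candidates = c(4, 8)),
                 "edge")
})

test_that("monthly GWR recovers a smooth spatially varying slope field", {
  # full-width domain so the 15 km slope field shows several independent
  # features across the 40-site network
  cfg <- domain_config(n_monitors = 40, n_days = 90, start_month = 6L,
                       seed = 4)
  st <- synth_study(cfg)
  tab <- prepare_study(st)$table
  fit <- suppressWarnings(fit_stage1(tab, true_spec()))
  rdf <- stage1_residuals(fit, tab)
  bw <- as.numeric(suppressWarnings(select_bandwidth(rdf, gwr_spec())))
  targets <- data.frame(loc_id = st$monitors$cell_id,
                        x = st$monitors$x, y = st$monitors$y)
  s2 <- suppressWarnings(fit_stage2(rdf, targets, gwr_spec(), bandwidth = bw))
  truth <- st$truth$beta1[as.character(targets$loc_id)]
  expect_equal(length(s2$months), 3)          # Jun, Jul, Aug
  cors <- vapply(s2$months, function(co) cor(co$beta1, truth), numeric(1))
  expect_true(all(cors > 0.3))
  # the month-averaged field (beta1 is static) is recovered well
  avg <- rowMeans(vapply(s2$months, function(co) co$beta1,
                         numeric(nrow(targets))))
  expect_gt(cor(avg, truth), 0.7)
})

test_that("stage-2 correction composes, floors and falls back correctly", {
  # zero correction: final equals stage 1
  dat <- make_month(seed = 45)
  dat$resid <- 0
  targets <- data.frame(loc_id = c("a", "b"), x = c(10, 30), y = c(10, 30))
  s2 <- fit_stage2(dat, targets, gwr_spec(), bandwidth = 10)
  p1 <- data.frame(loc_id = c("a", "b", "a"),
                   date = c("2006-07-03", "2006-07-04", "2006-07-05"),
                   aod = c(0.3, 0.5, NA), pred1 = c(12, 14, 9))
  out <- predict_stage2(p1, s2)
  expect_equal(nrow(out), 2)                  # missing-AOD row dropped
  expect_equal(out$pred, out$pred1)
  expect_true(all(out$provenance == "two_stage"))

  # a month not fitted falls back to stage 1 with provenance
  p1b <- data.frame(loc_id = "a", date = "2006-09-01", aod = 0.4, pred1 = 11)
  outb <- predict_stage2(p1b, s2)
  expect_equal(outb$pred, 11)
  expect_equal(outb$provenance, "stage1_only")

  # physically impossible negatives are floored at zero and counted
  dat2 <- make_month(seed = 46)
  dat2$resid <- -30
  s2n <- fit_stage2(dat2, targets, gwr_spec(), bandwidth = 10)
  outn <- predict_stage2(data.frame(loc_id = "a", date = "2006-07-03",
                                    aod = 0.3, pred1 = 5), s2n)
  expect_equal(outn$pred, 0)
  expect_equal(attr(outn, "n_floored"), 1)
})

test_that("shrinking bandwidth tightens the in-sample fit", {
  fx <- summer_study()
  fit <- suppressWarnings(fit_stage1(fx$table, true_spec()))
  rdf <- stage1_residuals(fit, fx$table)
  one <- rdf[rdf$month == rdf$month[1], ]
  targets <- unique(data.frame(loc_id = one$site_id, x = one$x, y = one$y))
  rmspe_at <- function(bw) {
    co <- fit_gwr_month(one, targets, gwr_spec(), bandwidth = bw)
    i <- match(one$site_id, co$loc_id)
    sqrt(mean((one$resid - (co$beta0[i] + co$beta1[i] * one$aod))^2))
  }
  expect_lt(rmspe_at(2), rmspe_at(20))
})
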