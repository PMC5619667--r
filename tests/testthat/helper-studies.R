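# Shared fixtures, built once per test run.  All synthetic: nothing on disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Mid-sized summer study with an active beta1 field; used by the stage-1,
# stage-2 and evaluation tests.
summer_study <- function() {
  memo("summer_study", function() {
    cfg <- domain_config(domain_size_km = 30, n_monitors = 40, n_days = 90,
                         start_month = 6L, seed = 4)
    st <- synth_study(cfg)
    prep <- suppressWarnings(prepare_study(st))
    list(config = cfg, study = st, table = prep$table, env = prep$env)
  })
}

true_spec <- function() {
  stage1_spec(fixed = c("aod", "rh", "elevation", "road_length",
                        "forest_cover", "point_emissions"),
              random = c("aod", "rh"))
}

# A small hand-sized analysis-like table for metric and fold tests.
toy_table <- function(n = 40, seed = 99) {
  set.seed(seed)
  data.frame(
    site_id = rep(sprintf("S%02d", 1:8), length.out = n),
    date = rep(as.character(seq(as.Date("2006-06-01"), by = "day",
                                length.out = ceiling(n / 8))), each = 8)[1:n],
    x = rep(1:8, length.out = n), y = rep(1:8, length.out = n),
    pm25 = 10 + rnorm(n), aod = runif(n, 0.1, 0.5), rh = runif(n, 40, 60),
    stringsAsFactors = FALSE
  )
}
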