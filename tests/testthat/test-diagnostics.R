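# A season-free, gradient-free climate with constant f_t: every month and
# every column should look statistically alike.
flat_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- make_grid(0, 0.5, 0, 1, 0.25) # 2 x 4 cells
      proc <- cwv_process(mean = 58, amplitude = 0, autocorr = 0.9,
                          noise_sd = 2, bounds = c(40, 75))
      clim <- simulate_climate(
        grid, n_hours = 17544, process = proc,
        ft = ft_params(mean = 0.13, lon_gradient = 0,
                       seasonal_amplitude = 0, sd = 0),
        seed = 31
      )
      curve <- build_quantile_curve(clim$hourly)
      cf <- counterfactual_series(clim$hourly, curve, clim$ft)
      cache <<- list(grid = grid, clim = clim,
                     summary = suppressMessages(reduction_summary(cf)))
    }
    cache
  }
})

test_that("seasonal cycle has 12 entries with an ordered quartile band", {
  sc <- seasonal_cycle(flat_run()$summary)
  expect_equal(nrow(sc), 12)
  expect_equal(sc$month, 1:12)
  ok <- stats::complete.cases(sc)
  expect_true(all(sc$reduction_lower[ok] <= sc$reduction_median[ok]))
  expect_true(all(sc$reduction_median[ok] <= sc$reduction_upper[ok]))
})

test_that("a season-free constant-ft climate gives a flat seasonal cycle", {
  sc <- seasonal_cycle(flat_run()$summary)
  expect_lt(diff(range(sc$reduction_median)), 15)
})

test_that("months of peak transpired fraction show the largest cwv reduction", {
  grid <- make_grid(0, 0.5, 0, 0.5, 0.25)
  clim <- simulate_climate(
    grid, n_hours = 8760,
    process = cwv_process(amplitude = 0),
    ft = ft_params(mean = 0.13, lon_gradient = 0,
                   seasonal_amplitude = 0.05, peak_month = 8, sd = 0),
    seed = 9
  )
  cf <- counterfactual_cwv(clim$hourly, clim$ft)
  monthly_red <- cf |>
    dplyr::mutate(month = lubridate::month(time)) |>
    dplyr::summarise(red = 100 * (1 - sum(cwv_t) / sum(cwv)), .by = month)
  expect_equal(monthly_red$month[which.max(monthly_red$red)], 8)
})

test_that("spatial profile is flat for a homogeneous run and covers each column once", {
  run <- flat_run()
  sp <- spatial_profile(run$summary, run$grid, "longitude")
  expect_equal(nrow(sp), attr(run$grid, "nlon"))
  expect_equal(sum(sp$n_cells), nrow(run$grid))
  expect_lt(diff(range(sp$mean_reduction_pct)), 15)
  sp_lat <- spatial_profile(run$summary, run$grid, "latitude")
  expect_equal(nrow(sp_lat), attr(run$grid, "nlat"))
})

test_that("a westward ft gradient makes the western reduction largest", {
  grid <- make_grid(0, 0.5, 0, 1, 0.25)
  clim <- simulate_climate(
    grid, n_hours = 17544,
    process = cwv_process(mean = 58, amplitude = 0, autocorr = 0.9,
                          noise_sd = 2, bounds = c(40, 75)),
    ft = ft_params(mean = 0.13, lon_gradient = 0.12,
                   seasonal_amplitude = 0, sd = 0),
    seed = 13
  )
  curve <- build_quantile_curve(clim$hourly)
  cf <- counterfactual_series(clim$hourly, curve, clim$ft)
  s <- suppressMessages(reduction_summary(cf))
  sp <- spatial_profile(s, grid, "longitude")
  expect_gt(sp$mean_reduction_pct[1], sp$mean_reduction_pct[nrow(sp)])
})

test_that("mean transpired fraction is reported in percent", {
  expect_equal(mean_transpired_fraction(tibble::tibble(ft = rep(0.13, 10))), 13)
  expect_equal(mean_transpired_fraction(tibble::tibble(ft = rep(0, 5))), 0)
  ft <- simulate_ft(make_grid(0, 1, 0, 1, 0.25), ft_params(), seed = 1)
  expect_lt(abs(mean_transpired_fraction(ft) - 13), 0.5)
  expect_error(mean_transpired_fraction(tibble::tibble(ft = 2)), "\\[0, 1\\]")
})

test_that("post-event cwv deltas are zero for a constant cwv series", {
  n <- 200
  h <- tibble::tibble(
    time = as.POSIXct("2003-01-01", tz = "UTC") + 3600 * (seq_len(n) - 1),
    cell_id = 1L,
    cwv = 65,
    precip = rep(c(rep(0, 19), 2), 10)
  )
  chk <- post_event_cwv_change(h)
  expect_gt(chk$summary$n_events, 0)
  expect_true(all(chk$deltas$delta == 0))
  expect_equal(chk$summary$mean_delta, 0)
})

test_that("an injected post-event cwv drop is recovered", {
  n <- 2400
  drop <- 4
  cwv <- rep(65, n)
  precip <- numeric(n)
  events <- seq(20, n - 20, by = 24)
  precip[events] <- 2
  for (i in events) cwv[(i + 1):(i + 6)] <- 65 - drop
  h <- tibble::tibble(
    time = as.POSIXct("2003-01-01", tz = "UTC") + 3600 * (seq_len(n) - 1),
    cell_id = 1L, cwv = cwv, precip = precip
  )
  chk <- post_event_cwv_change(h, event_threshold = 1, window = 3)
  expect_equal(chk$summary$mean_delta, -drop)
  expect_lt(chk$summary$ci_upper, 0)
})

test_that("a threshold above all rates yields an empty event set with warning", {
  h <- tibble::tibble(
    time = as.POSIXct("2003-01-01", tz = "UTC") + 3600 * (0:99),
    cell_id = 1L, cwv = 60, precip = 0.1
  )
  expect_warning(chk <- post_event_cwv_change(h, event_threshold = 50),
                 "no qualifying")
  expect_equal(nrow(chk$deltas), 0)
  expect_equal(chk$summary$n_events, 0L)
})
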