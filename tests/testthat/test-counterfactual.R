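hourly_toy <- function(n_hours = 48, cwv = 65, cells = 1:2) {
  tidyr::expand_grid(
    time = as.POSIXct("2003-01-01", tz = "UTC") + 3600 * (seq_len(n_hours) - 1),
    cell_id = cells
  ) |>
    dplyr::mutate(cwv = cwv)
}

ft_const <- function(value, cells = 1:2) {
  tidyr::expand_grid(cell_id = cells, month = 1:12) |>
    dplyr::mutate(ft = value)
}

test_that("counterfactual cwv scales by 1 - ft per cell and month", {
  h <- hourly_toy(cwv = 70)
  expect_equal(counterfactual_cwv(h, ft_const(0))$cwv_t, h$cwv)
  expect_true(all(counterfactual_cwv(h, ft_const(1))$cwv_t == 0))
  expect_equal(counterfactual_cwv(h, ft_const(0.13))$cwv_t,
               rep(70 * 0.87, nrow(h)))
})

test_that("missing (cell, month) transpired fractions are reported", {
  h <- hourly_toy()
  ft <- ft_const(0.1)[-1, ] # drop (cell 1, month 1)
  expect_error(counterfactual_cwv(h, ft), "\\(1, 1\\)")
  expect_error(counterfactual_cwv(h, ft_const(1.5)), "\\[0, 1\\]")
})

test_that("quantile ratio follows the published worked example and conventions", {
  curve <- fig2_fixture_curve()
  expect_equal(quantile_ratio(curve, 65, 65, 50), 1)
  expect_equal(quantile_ratio(curve, 65, 60, 50), 0.4 / 1.5)
  # both quartiles in the dry regime -> factor 1 by the 0/0 convention
  expect_equal(quantile_ratio(curve, 20, 10, 50), 1)
  expect_error(quantile_ratio(curve, 60, 65, 50), "exceed")
})

test_that("reduced precipitation is the elementwise product with f_q", {
  curve <- fig2_fixture_curve()
  h <- hourly_toy(n_hours = 24, cwv = 65) |>
    counterfactual_cwv(ft_const(5 / 65)) # cwv_t = 60 exactly
  h$precip <- 2.0
  out <- reduced_precip(h, curve, q = 50)
  expect_equal(out$f_50, rep(0.4 / 1.5, nrow(out)))
  expect_equal(out$p_t_50, out$precip * out$f_50)
  # dry hours stay dry
  h$precip <- 0
  expect_true(all(reduced_precip(h, curve, q = 50)$p_t_50 == 0))
})

test_that("a factor of 0.25 quarters the rate", {
  curve <- build_quantile_curve(data.frame(
    cwv = c(rep(60.5, 8), rep(65.5, 8)),
    precip = c(rep(0.5, 8), rep(2.0, 8))
  ))
  h <- hourly_toy(n_hours = 24, cwv = 65.5) |>
    counterfactual_cwv(ft_const(5 / 65.5)) # cwv_t = 60.5
  h$precip <- 2.0
  out <- reduced_precip(h, curve, q = 50)
  expect_equal(unique(out$f_50), 0.25)
  expect_equal(unique(out$p_t_50), 0.5)
})

test_that("daily aggregation sums hourly rates into mm per day", {
  h <- hourly_toy(n_hours = 24, cwv = 50, cells = 1)
  h$precip <- 0.1
  d <- aggregate_precip(h, "daily")
  expect_equal(nrow(d), 1)
  expect_equal(d$precip, 2.4)

  h$precip <- 0
  expect_equal(aggregate_precip(h, "daily")$precip, 0)
})

test_that("aggregation matches brute-force accumulation on a mixed 48-h series", {
  set.seed(5)
  h <- hourly_toy(n_hours = 48, cwv = 60, cells = 1:2)
  h$precip <- round(rexp(nrow(h), 2), 3)
  d <- aggregate_precip(h, "daily")
  for (cell in 1:2) {
    day1 <- sum(h$precip[h$cell_id == cell][1:24])
    day2 <- sum(h$precip[h$cell_id == cell][25:48])
    got <- d$precip[d$cell_id == cell]
    expect_equal(got, c(day1, day2))
  }
  # area-wide series is the mean over cells
  am <- area_mean(d)
  expect_equal(am$precip,
               (d$precip[d$cell_id == 1] + d$precip[d$cell_id == 2]) / 2)
})

test_that("incomplete trailing periods are dropped with a warning", {
  h <- hourly_toy(n_hours = 30, cwv = 50, cells = 1)
  h$precip <- 1
  expect_warning(d <- aggregate_precip(h, "daily"), "incomplete")
  expect_equal(nrow(d), 1)
  expect_error(aggregate_precip(h[0, ], "daily"), "empty")
})

test_that("wet-day filter keeps days at or above 0.01 mm", {
  d <- tibble::tibble(
    cell_id = 1L,
    period_start = as.POSIXct("2003-01-01", tz = "UTC") + 86400 * 0:3,
    precip = c(0, 0.02, 0.005, 3.1)
  )
  expect_equal(nrow(filter_wet_days(d)), 2)
  expect_equal(nrow(filter_wet_days(d, precip, cutoff = 0.01)), 2)
  expect_true(0.02 %in% filter_wet_days(d)$precip)
  boundary <- tibble::tibble(precip = c(0.005, 0.01))
  expect_equal(filter_wet_days(boundary)$precip, 0.01)
  expect_error(filter_wet_days(d, precip, cutoff = -1), ">= 0")
})

test_that("percent reduction reproduces the published event-size arithmetic", {
  expect_equal(percent_reduction(1, 1), 0)
  expect_equal(round(percent_reduction(4.30, 1.37)), 68)
  expect_equal(round(percent_reduction(4.30, 1.41)), 67)
  expect_message(out <- percent_reduction(c(0, 2), c(0, 1)), "zero observed")
  expect_equal(out, c(NA, 50))
  expect_error(percent_reduction(c(0, 0), c(0, 0)), "all zero")
})

test_that("with no moisture removed the whole pipeline is the identity", {
  clim <- small_climate()
  curve <- build_quantile_curve(clim$hourly)
  ft0 <- dplyr::mutate(clim$ft, ft = 0)
  cf <- counterfactual_series(clim$hourly, curve, ft0)
  expect_identical(cf$cwv_t, cf$cwv)
  for (q in c(25, 50, 75)) {
    expect_identical(cf[[paste0("p_t_", q)]], cf$precip)
  }
  s <- suppressMessages(reduction_summary(cf))
  expect_true(all(s$headline$annual_reduction_median == 0))
  expect_true(all(s$headline$monthly_reduction_median == 0))
  expect_true(all(s$events$event_reduction_pct == 0))
  expect_equal(s$cwv_reduction_pct, 0)
})

test_that("a monotone curve bounds factors in [0,1] and reductions in [0,100]", {
  clim <- small_climate()
  curve <- fig2_fixture_curve() # strictly increasing in cwv by construction
  cf <- counterfactual_series(clim$hourly, curve, clim$ft)
  for (q in c(25, 50, 75)) {
    fq <- cf[[paste0("f_", q)]]
    expect_true(all(fq >= 0 & fq <= 1))
  }
  s <- suppressMessages(reduction_summary(cf))
  red <- unlist(s$annual[paste0("red_", c(25, 50, 75))])
  expect_true(all(red >= 0 & red <= 100, na.rm = TRUE))
  expect_true(all(s$annual$p_t_50 <= s$annual$precip))
})
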