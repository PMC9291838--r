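test_that("bins follow the >5-point validity rule and the cwv cap", {
  data <- data.frame(
    cwv = c(rep(50.5, 5), rep(51.5, 6), 73.0, 73.2),
    precip = c(rep(1, 5), rep(2, 6), 9, 9)
  )
  curve <- build_quantile_curve(data)
  b50 <- curve[curve$bin_lower == 50, ]
  b51 <- curve[curve$bin_lower == 51, ]
  expect_equal(b50$count, 5)
  expect_false(b50$valid)
  expect_true(b51$valid)
  # values at or above 73 mm are excluded entirely
  expect_false(any(curve$bin_lower >= 73))
  expect_equal(sum(curve$count), 11)
})

test_that("quartiles use the linear-interpolation estimator", {
  const <- data.frame(cwv = rep(40.2, 8), precip = rep(3.3, 8))
  cc <- build_quantile_curve(const)
  expect_equal(c(cc$p25, cc$p50, cc$p75), c(3.3, 3.3, 3.3))

  seven <- data.frame(cwv = rep(55.5, 7), precip = 0:6)
  cs <- build_quantile_curve(seven)
  expect_equal(c(cs$p25, cs$p50, cs$p75), c(1.5, 3, 4.5))
})

test_that("curve matches a brute-force sort-and-interpolate oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 1e4
    cwv <- runif(n, 30, 76)
    precip <- ifelse(cwv > 60, rexp(n, 1 / pmax(0.1, cwv - 60)), 0)
    curve <- build_quantile_curve(data.frame(cwv = cwv, precip = precip))
    oracle <- brute_force_curve(cwv, precip)
    expect_equal(curve$bin_lower, oracle$bin_lower)
    expect_equal(curve$count, oracle$count)
    expect_equal(curve$p25, oracle$p25)
    expect_equal(curve$p50, oracle$p50)
    expect_equal(curve$p75, oracle$p75)
    expect_equal(curve$valid, oracle$valid)
  }
})

test_that("quartile ordering p25 <= p50 <= p75 holds for arbitrary inputs", {
  set.seed(99)
  for (i in 1:5) {
    n <- sample(50:2000, 1)
    cwv <- runif(n, 0, 80)
    precip <- rgamma(n, shape = 0.3, scale = 2)
    curve <- suppressWarnings(
      build_quantile_curve(data.frame(cwv = cwv, precip = precip))
    )
    expect_true(all(curve$p25 <= curve$p50 & curve$p50 <= curve$p75))
    expect_true(all(curve$p25 >= 0))
  }
})

test_that("degenerate curve inputs are handled", {
  expect_error(build_quantile_curve(data.frame(cwv = numeric(0),
                                               precip = numeric(0))),
               "empty")
  expect_warning(
    build_quantile_curve(data.frame(cwv = c(40, 50), precip = c(1, 2))),
    "min_count"
  )
  expect_error(
    build_quantile_curve(data.frame(cwv = 40, precip = -1)),
    ">= 0"
  )
})

test_that("lookup is piecewise constant with lower-valid-bin fallback", {
  data <- data.frame(
    cwv = c(rep(60.5, 7), rep(61.5, 3), rep(64.5, 7)),
    precip = c(rep(1, 7), rep(5, 3), rep(9, 7))
  )
  curve <- build_quantile_curve(data) # valid bins: 60 (1), 64 (9); 61 invalid
  expect_equal(lookup_quantile(curve, 60.9, 50), 1) # inside a valid bin
  expect_equal(lookup_quantile(curve, 61.5, 50), 1) # invalid bin -> lower valid
  expect_equal(lookup_quantile(curve, 63.0, 50), 1) # absent bin -> lower valid
  expect_equal(lookup_quantile(curve, 64.2, 50), 9)
  expect_equal(lookup_quantile(curve, 99, 50), 9)  # above top -> top valid bin
  expect_equal(lookup_quantile(curve, 10, 50), 0)  # below all valid bins -> 0
  expect_error(lookup_quantile(curve, 65, q = 40), "must be one of")
})

test_that("the fixture pickup curve reproduces the published worked example", {
  curve <- fig2_fixture_curve()
  p65 <- lookup_quantile(curve, 65, 50)
  p60 <- lookup_quantile(curve, 60, 50)
  p70 <- lookup_quantile(curve, 70, 50)
  expect_equal(p65, 1.5)
  expect_equal(p65 - p60, 1.1)
  expect_equal(p70 - p65, 8.7)
})

test_that("perfect linear and exponential relations give R^2 = 1", {
  w <- seq(1, 50, by = 0.5)
  lin <- fit_linear(data.frame(cwv = w, precip = 2 * w + 1))
  expect_equal(lin$r_squared, 1)
  expect_equal(unname(lin$coef["slope"]), 2, tolerance = 1e-8)

  expf <- fit_exponential(data.frame(cwv = w, precip = 0.01 * exp(0.1 * w)))
  expect_equal(expf$r_squared, 1, tolerance = 1e-6)
  expect_equal(unname(expf$coef["b"]), 0.1, tolerance = 1e-4)
})

test_that("constant cwv makes both fits degenerate", {
  bad <- data.frame(cwv = rep(5, 10), precip = rnorm(10))
  expect_error(fit_linear(bad), "constant")
  expect_error(fit_exponential(bad), "constant")
})

test_that("pickup-law data favor the exponential over the linear fit", {
  clim <- small_climate()
  lin <- fit_linear(clim$hourly)
  expf <- fit_exponential(clim$hourly)
  expect_gt(expf$r_squared, lin$r_squared)
  expect_lte(lin$r_squared, 1)

  # broom-style accessors
  expect_named(tidy(lin), c("term", "estimate"))
  expect_equal(glance(expf)$kind, "exponential")
})
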