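# Synthetic gridded climate generator: seasonal AR(1) column water vapor,
# threshold pickup-law precipitation, and monthly transpired-fraction fields.

derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * k) %% 2147483629)
}

#' Parameters of the seasonal AR(1) column-water-vapor process
#'
#' Hourly column water vapor (cwv, mm) in each cell is simulated as
#' `mean + amplitude * cos(2*pi*(h - phase)/8760) + x_h`, where `h` is the
#' hour of year and `x_h` is a stationary AR(1) noise with lag-1 coefficient
#' `autocorr` and innovation standard deviation `noise_sd`; the series is
#' then clipped to `bounds`. Tropical cwv sits in a narrow absolute range, so
#' the defaults give a wet-season peak in mid-January and values mostly
#' between 35 and 70 mm.
#'
#' @param mean Mean cwv level (mm).
#' @param amplitude Seasonal half-range (mm, >= 0).
#' @param phase Hour of year at which the seasonal cycle peaks (default 360,
#'   i.e. mid-January).
#' @param autocorr Hourly lag-1 autocorrelation, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation (mm, >= 0). The stationary
#'   standard deviation of the AR(1) component is
#'   `noise_sd / sqrt(1 - autocorr^2)`.
#' @param bounds Length-2 clipping bounds (mm).
#' @return A list of class `cwv_process`.
#' @export
cwv_process <- function(mean = 52, amplitude = 8, phase = 360,
                        autocorr = 0.95, noise_sd = 2,
                        bounds = c(20, 75)) {
  if (!is.finite(mean)) stop("`mean` must be finite", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (autocorr < 0 || autocorr >= 1) {
    stop("`autocorr` must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("`bounds` must be increasing length-2", call. = FALSE)
  }
  structure(
    list(
      mean = mean, amplitude = amplitude, phase = phase,
      autocorr = autocorr, noise_sd = noise_sd, bounds = as.numeric(bounds)
    ),
    class = "cwv_process"
  )
}

#' Parameters of the precipitation pickup law
#'
#' Hourly precipitation is generated from cwv by a threshold ("pickup") law:
#' hours at or below the critical cwv `w_c` are exactly dry, and above it
#' `p = a * (cwv - w_c)^beta * X`, with `X` a unit-median lognormal magnitude
#' noise. The conditional median at cwv `w` is therefore exactly
#' `a * max(0, w - w_c)^beta` for any noise level. The noise spread tapers
#' with distance above threshold (`sdlog` falls linearly from `sdlog_low` at
#' `w_c` to `sdlog_high` at `w_c + sdlog_taper`), so the conditional
#' interquartile band narrows, in relative terms, as cwv rises -- the lower
#' quartile curve is relatively steeper than the median, as in observed
#' tropical pickup plots.
#'
#' @param w_c Critical cwv (mm, >= 0) below which hours are dry.
#' @param a Scale (mm/h per mm^beta, > 0). The default `0.06` puts the median
#'   at 65 mm cwv at `0.06 * 5^2 = 1.5` mm/h.
#' @param beta Exponent (>= 1).
#' @param sdlog_low,sdlog_high,sdlog_taper Lognormal `sdlog` of the magnitude
#'   noise at threshold, its asymptote, and the taper length (mm). Set both
#'   sdlogs to 0 to disable noise.
#' @return A list of class `pickup_law`.
#' @export
pickup_law <- function(w_c = 60, a = 0.06, beta = 2,
                       sdlog_low = 0.6, sdlog_high = 0.3, sdlog_taper = 10) {
  if (w_c < 0) stop("`w_c` must be >= 0", call. = FALSE)
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (beta < 1) stop("`beta` must be >= 1", call. = FALSE)
  if (sdlog_low < 0 || sdlog_high < 0 || sdlog_taper <= 0) {
    stop("noise parameters must be nonnegative (taper > 0)", call. = FALSE)
  }
  structure(
    list(
      w_c = w_c, a = a, beta = beta,
      sdlog_low = sdlog_low, sdlog_high = sdlog_high, sdlog_taper = sdlog_taper
    ),
    class = "pickup_law"
  )
}

#' Conditional median precipitation implied by a pickup law
#'
#' Closed form `a * max(0, cwv - w_c)^beta`, the exact conditional median of
#' precipitation generated by [simulate_precip()] at fixed cwv (the magnitude
#' noise has unit median).
#'
#' @param law A [pickup_law()].
#' @param cwv Numeric vector of cwv values (mm).
#' @return Numeric vector of median precipitation rates (mm/h).
#' @export
pickup_median <- function(law, cwv) {
  stopifnot(inherits(law, "pickup_law"))
  law$a * pmax(0, cwv - law$w_c)^law$beta
}

pickup_sdlog <- function(law, cwv) {
  frac <- pmin(1, pmax(0, cwv - law$w_c) / law$sdlog_taper)
  law$sdlog_low + (law$sdlog_high - law$sdlog_low) * frac
}

hour_of_year <- function(time) {
  (lubridate::yday(time) - 1) * 24 + lubridate::hour(time)
}

#' Simulate hourly column water vapor on a grid
#'
#' Generates one seasonal AR(1) cwv series per grid cell (cells are
#' independent; no spatial correlation is emulated). Reproducible: the same
#' seed, grid and parameters give bit-identical output.
#'
#' @param grid A [make_grid()] grid.
#' @param n_hours Number of hourly steps (>= 1).
#' @param process A [cwv_process()].
#' @param seed Integer seed.
#' @param start First timestamp (UTC), default `"2003-01-01"`.
#' @return A tibble with columns `time` (POSIXct UTC), `cell_id`, `cwv` (mm),
#'   ordered by cell then time.
#' @export
simulate_cwv <- function(grid, n_hours, process = cwv_process(), seed = 1L,
                         start = "2003-01-01") {
  stopifnot(inherits(grid, "pickup_grid"), inherits(process, "cwv_process"))
  if (n_hours < 1) stop("`n_hours` must be >= 1", call. = FALSE)
  n_hours <- as.integer(n_hours)
  time <- lubridate::as_datetime(start, tz = "UTC") + 3600 * (seq_len(n_hours) - 1)
  seasonal <- process$mean +
    process$amplitude * cos(2 * pi * (hour_of_year(time) - process$phase) / 8760)

  rho <- process$autocorr
  sd_stat <- if (process$noise_sd > 0) process$noise_sd / sqrt(1 - rho^2) else 0
  n_cells <- nrow(grid)
  withr::with_seed(derive_seed(seed, 1L), {
    vals <- lapply(seq_len(n_cells), function(i) {
      if (process$noise_sd == 0) {
        x <- numeric(n_hours)
      } else {
        innov <- stats::rnorm(n_hours, 0, process$noise_sd)
        x <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                      init = stats::rnorm(1, 0, sd_stat)))
      }
      pmin(process$bounds[2], pmax(process$bounds[1], seasonal + x))
    })
  })
  tibble::tibble(
    time = rep(time, times = n_cells),
    cell_id = rep(grid$cell_id, each = n_hours),
    cwv = unlist(vals, use.names = FALSE)
  )
}

#' Simulate hourly precipitation from cwv via the pickup law
#'
#' Applies the threshold pickup law to an hourly cwv field: hours with
#' `cwv <= w_c` are exactly dry; above threshold the rate is the law's median
#' times a unit-median lognormal draw. Reproducible given the seed.
#'
#' @param cwv_field Tibble with columns `cell_id` and `cwv` (e.g. from
#'   [simulate_cwv()]); any other columns are carried through.
#' @param law A [pickup_law()].
#' @param seed Integer seed.
#' @return The input tibble with a `precip` column (mm/h) appended.
#' @export
simulate_precip <- function(cwv_field, law = pickup_law(), seed = 1L) {
  stopifnot(inherits(law, "pickup_law"))
  cwv <- cwv_field$cwv
  if (is.null(cwv)) stop("`cwv_field` must have a `cwv` column", call. = FALSE)
  if (any(!is.finite(cwv)) || any(cwv < 0)) {
    stop("`cwv` must be finite and nonnegative", call. = FALSE)
  }
  med <- pickup_median(law, cwv)
  wet <- cwv > law$w_c
  p <- numeric(length(cwv))
  if (any(wet)) {
    sdlog <- pickup_sdlog(law, cwv[wet])
    if (all(sdlog == 0)) {
      p[wet] <- med[wet]
    } else {
      withr::with_seed(derive_seed(seed, 2L), {
        p[wet] <- med[wet] * exp(stats::rnorm(sum(wet), 0, sdlog))
      })
    }
  }
  dplyr::mutate(cwv_field, precip = p)
}

#' Parameters of the monthly transpired-fraction field
#'
#' The transpired fraction `f_t` is the share of a cell's column water vapor
#' attributed to upwind tree transpiration in a given calendar month. The
#' generated field is `mean` plus a longitudinal gradient (increasing
#' westward, reflecting the east-to-west moisture transport that accumulates
#' transpired vapor downwind), a seasonal cosine peaking in the dry season,
#' and white noise; values are clipped to `[0, 1]`. Gradient, season and
#' noise are mean-zero by construction, so the field mean stays at `mean`.
#'
#' @param mean Area-time mean fraction, in `(0, 1)` (default 0.13).
#' @param lon_gradient Total west-minus-east difference in `f_t` across the
#'   box (>= 0; 0 disables the gradient).
#' @param seasonal_amplitude Half-range of the seasonal cycle (>= 0).
#' @param peak_month Calendar month of maximum `f_t` (default 8, austral dry
#'   season).
#' @param sd Standard deviation of per-(cell, month) noise (>= 0).
#' @return A list of class `ft_params`.
#' @export
ft_params <- function(mean = 0.13, lon_gradient = 0.08,
                      seasonal_amplitude = 0.03, peak_month = 8, sd = 0.01) {
  if (mean <= 0 || mean >= 1) stop("`mean` must be in (0, 1)", call. = FALSE)
  if (lon_gradient < 0 || seasonal_amplitude < 0 || sd < 0) {
    stop("gradient, seasonal amplitude and sd must be >= 0", call. = FALSE)
  }
  structure(
    list(
      mean = mean, lon_gradient = lon_gradient,
      seasonal_amplitude = seasonal_amplitude,
      peak_month = as.integer(peak_month), sd = sd
    ),
    class = "ft_params"
  )
}

#' Simulate the monthly transpired-fraction field
#'
#' @param grid A [make_grid()] grid.
#' @param params An [ft_params()] object.
#' @param seed Integer seed.
#' @return A tibble with columns `cell_id`, `month` (1--12), `ft` in `[0, 1]`,
#'   one row per (cell, calendar month).
#' @export
simulate_ft <- function(grid, params = ft_params(), seed = 1L) {
  stopifnot(inherits(grid, "pickup_grid"), inherits(params, "ft_params"))
  west <- attr(grid, "west")
  east <- attr(grid, "east")
  # scaled position in (-0.5, 0.5): negative in the west
  u <- (grid$lon - (west + east) / 2) / (east - west)
  base <- params$mean - params$lon_gradient * u
  out <- tidyr::expand_grid(cell_id = grid$cell_id, month = 1:12)
  out$ft <- base[match(out$cell_id, grid$cell_id)] +
    params$seasonal_amplitude *
      cos(2 * pi * (out$month - params$peak_month) / 12)
  if (params$sd > 0) {
    withr::with_seed(derive_seed(seed, 3L), {
      out$ft <- out$ft + stats::rnorm(nrow(out), 0, params$sd)
    })
  }
  out$ft <- pmin(1, pmax(0, out$ft))
  out
}

#' Simulate a full synthetic study data set
#'
#' Convenience wrapper running [simulate_cwv()], [simulate_precip()] and
#' [simulate_ft()] with sub-seeds derived from one master seed.
#'
#' @inheritParams simulate_cwv
#' @param law A [pickup_law()].
#' @param ft An [ft_params()] object.
#' @return A list of class `synthetic_climate` with elements `hourly`
#'   (tibble `time`, `cell_id`, `cwv`, `precip`), `ft` (tibble from
#'   [simulate_ft()]), `grid`, `process`, `law`.
#' @export
simulate_climate <- function(grid, n_hours, process = cwv_process(),
                             law = pickup_law(), ft = ft_params(),
                             seed = 1L, start = "2003-01-01") {
  hourly <- simulate_cwv(grid, n_hours, process, seed = seed, start = start)
  hourly <- simulate_precip(hourly, law, seed = seed)
  ft_field <- simulate_ft(grid, ft, seed = seed)
  structure(
    list(hourly = hourly, ft = ft_field, grid = grid,
         process = process, law = law),
    class = "synthetic_climate"
  )
}

#' @export
print.synthetic_climate <- function(x, ...) {
  cat(sprintf(
    "<synthetic_climate> %d cells x %d hours (%s to %s)\n",
    nrow(x$grid), length(unique(x$hourly$time)),
    format(min(x$hourly$time)), format(max(x$hourly$time))
  ))
  invisible(x)
}
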