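# Empirical precipitation--cwv relation: binned conditional quartile curves
# and linear/exponential fits.

#' Bin hourly precipitation by column water vapor and compute quartiles
#'
#' Builds the empirical conditional quartile curve of hourly precipitation
#' versus column water vapor: observations are assigned to left-closed,
#' right-open cwv bins (`[k, k + bin_width)`, `k = floor(cwv / bin_width) *
#' bin_width`), values with `cwv >= max_cwv` are discarded, and within each
#' bin the 25th, 50th and 75th percentiles of precipitation are computed with
#' the linear-interpolation ("type 7") estimator. All hours enter the curve,
#' including dry ones -- the near-zero medians at low cwv are real features
#' of the relation, not missing data. Bins with fewer than `min_count`
#' observations are flagged invalid.
#'
#' @param data Data frame with one row per (cell, hour) observation.
#' @param cwv,precip Columns holding cwv (mm) and precipitation (mm/h);
#'   unquoted, defaults `cwv` and `precip`.
#' @param bin_width Bin width in mm (default 1).
#' @param min_count Minimum observations for a bin to be valid (default 6,
#'   i.e. strictly more than five points).
#' @param max_cwv Upper cwv cutoff in mm (default 73); values at or above it
#'   are excluded.
#' @return A tibble of class `quantile_curve` with columns `bin_lower`,
#'   `count`, `p25`, `p50`, `p75`, `valid`, one row per occupied bin, sorted
#'   by `bin_lower`. Attributes record `bin_width`, `min_count`, `max_cwv`.
#' @seealso [lookup_quantile()], [autoplot.quantile_curve()]
#' @export
build_quantile_curve <- function(data, cwv = cwv, precip = precip,
                                 bin_width = 1, min_count = 6, max_cwv = 73) {
  w <- dplyr::pull(data, {{ cwv }})
  p <- dplyr::pull(data, {{ precip }})
  if (length(w) != length(p)) stop("unequal series lengths", call. = FALSE)
  if (length(w) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(p))) {
    stop("cwv and precipitation must be finite", call. = FALSE)
  }
  if (any(p < 0)) stop("precipitation must be >= 0", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)

  keep <- w < max_cwv
  w <- w[keep]
  p <- p[keep]
  if (length(w) == 0) stop("no observations below `max_cwv`", call. = FALSE)

  out <- tibble::tibble(
    bin_lower = floor(w / bin_width) * bin_width,
    p = p
  ) |>
    dplyr::summarise(
      count = dplyr::n(),
      p25 = stats::quantile(p, 0.25, type = 7, names = FALSE),
      p50 = stats::quantile(p, 0.50, type = 7, names = FALSE),
      p75 = stats::quantile(p, 0.75, type = 7, names = FALSE),
      .by = bin_lower
    ) |>
    dplyr::mutate(valid = count >= min_count) |>
    dplyr::arrange(bin_lower)

  if (!any(out$valid)) {
    warning("all bins have fewer than `min_count` observations", call. = FALSE)
  }
  structure(out,
    class = c("quantile_curve", class(out)),
    bin_width = bin_width, min_count = min_count, max_cwv = max_cwv
  )
}

#' Look up a conditional quartile on a binned curve
#'
#' Piecewise-constant lookup: each cwv value maps to the quartile stored for
#' the bin containing it. If that bin is invalid or absent, the nearest valid
#' bin at lower cwv is used; with no valid bin below, the result is 0 (dry
#' below the observed pickup range). Values above the highest valid bin get
#' that bin's value.
#'
#' @param curve A [build_quantile_curve()] result with at least one valid bin.
#' @param cwv Numeric vector of cwv values (mm).
#' @param q Quartile, one of 25, 50, 75.
#' @return Numeric vector of precipitation rates (mm/h), same length as `cwv`.
#' @export
lookup_quantile <- function(curve, cwv, q = 50) {
  stopifnot(inherits(curve, "quantile_curve"))
  if (length(q) != 1L || !q %in% c(25, 50, 75)) {
    stop("`q` must be one of 25, 50, 75", call. = FALSE)
  }
  vb <- curve[curve$valid, , drop = FALSE]
  if (nrow(vb) == 0) stop("curve has no valid bin", call. = FALSE)
  vals <- vb[[paste0("p", q)]]
  idx <- findInterval(cwv, vb$bin_lower)
  out <- numeric(length(cwv))
  hit <- idx > 0
  out[hit] <- vals[idx[hit]]
  out
}

r_squared <- function(obs, fitted) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - fitted)^2) / ss_tot
}

new_pickup_fit <- function(kind, coef, r2, n) {
  structure(
    list(kind = kind, coef = coef, r_squared = r2, n = n),
    class = "pickup_fit"
  )
}

#' Linear and exponential fits of precipitation on column water vapor
#'
#' `fit_linear()` fits `p = c0 + c1 * cwv` by ordinary least squares.
#' `fit_exponential()` fits `p = a * exp(b * cwv)` by nonlinear least squares
#' on the original scale ([minpack.lm::nlsLM()]), initialized from a
#' log-linear fit on `log(p + 1e-6)` (the offset keeps the many dry hours
#' finite). Both report the coefficient of determination on the original,
#' untransformed scale, so the two R-squared values are directly comparable;
#' a sharply nonlinear pickup relation shows up as the exponential fit
#' explaining more variance than the linear one.
#'
#' @inheritParams build_quantile_curve
#' @return An object of class `pickup_fit` with elements `kind`
#'   (`"linear"` or `"exponential"`), `coef` (named parameters),
#'   `r_squared`, `n`. [generics::tidy()] and [generics::glance()] methods
#'   are provided.
#' @export
fit_linear <- function(data, cwv = cwv, precip = precip) {
  w <- dplyr::pull(data, {{ cwv }})
  p <- dplyr::pull(data, {{ precip }})
  check_fit_input(w, p)
  fit <- stats::lm(p ~ w)
  cf <- stats::coef(fit)
  new_pickup_fit(
    "linear",
    c(intercept = unname(cf[1]), slope = unname(cf[2])),
    r_squared(p, stats::fitted(fit)),
    length(w)
  )
}

#' @rdname fit_linear
#' @export
fit_exponential <- function(data, cwv = cwv, precip = precip) {
  w <- dplyr::pull(data, {{ cwv }})
  p <- dplyr::pull(data, {{ precip }})
  check_fit_input(w, p)
  start_fit <- stats::lm(log(p + 1e-6) ~ w)
  start <- list(
    a = exp(unname(stats::coef(start_fit)[1])),
    b = unname(stats::coef(start_fit)[2])
  )
  fit <- minpack.lm::nlsLM(
    p ~ a * exp(b * w),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  new_pickup_fit(
    "exponential",
    c(a = unname(cf["a"]), b = unname(cf["b"])),
    r_squared(p, stats::fitted(fit)),
    length(w)
  )
}

check_fit_input <- function(w, p) {
  if (length(w) != length(p)) stop("unequal series lengths", call. = FALSE)
  if (length(w) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(p))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(w) == 0) stop("cwv is constant; fit is degenerate", call. = FALSE)
  invisible(NULL)
}

#' @export
print.pickup_fit <- function(x, ...) {
  cat(sprintf("<pickup_fit> %s: %s; R^2 = %.3f (n = %d)\n",
              x$kind,
              paste(names(x$coef), signif(x$coef, 4), sep = " = ",
                    collapse = ", "),
              x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pickup_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.pickup_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, r.squared = x$r_squared, nobs = x$n)
}

#' Plot a conditional quartile curve
#'
#' Median line with interquartile ribbon over valid bins, values drawn at bin
#' centers.
#'
#' @param object A `quantile_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantile_curve <- function(object, ...) {
  vb <- dplyr::filter(tibble::as_tibble(object), .data$valid)
  bw <- attr(object, "bin_width")
  vb$center <- vb$bin_lower + bw / 2
  ggplot2::ggplot(vb, ggplot2::aes(x = .data$center)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), linewidth = 0.8) +
    ggplot2::labs(
      x = "column water vapor (mm)",
      y = expression(precipitation ~ (mm ~ h^{-1})),
      title = "Conditional quartiles of hourly precipitation"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
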