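# Monte Carlo estimator: resample observed precipitation conditionally on
# the counterfactual cwv, with replacement, preserving the conditional
# distribution (but not the temporal structure).

#' Build conditional precipitation pools per cwv bin
#'
#' Partitions observed hourly precipitation into 1-mm (by default) cwv bins
#' using the same binning conventions as [build_quantile_curve()]: bins are
#' `[k, k + bin_width)`, values with `cwv >= max_cwv` are discarded. Unlike
#' the quartile curve there is no minimum-count rule; sparse pools are legal
#' and empty bins are handled at sampling time.
#'
#' @inheritParams build_quantile_curve
#' @return A tibble of class `conditional_pool` with columns `bin_lower`,
#'   `count`, and `values` (list column of precipitation vectors), sorted by
#'   `bin_lower`.
#' @export
build_pool <- function(data, cwv = cwv, precip = precip,
                       bin_width = 1, max_cwv = 73) {
  w <- dplyr::pull(data, {{ cwv }})
  p <- dplyr::pull(data, {{ precip }})
  if (length(w) != length(p)) stop("unequal series lengths", call. = FALSE)
  if (length(w) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(p))) {
    stop("cwv and precipitation must be finite", call. = FALSE)
  }
  keep <- w < max_cwv
  if (!any(keep)) stop("no observations below `max_cwv`", call. = FALSE)
  out <- tibble::tibble(
    bin_lower = floor(w[keep] / bin_width) * bin_width,
    p = p[keep]
  ) |>
    dplyr::summarise(
      count = dplyr::n(),
      values = list(p),
      .by = "bin_lower"
    ) |>
    dplyr::arrange(.data$bin_lower)
  structure(out,
    class = c("conditional_pool", class(out)),
    bin_width = bin_width, max_cwv = max_cwv
  )
}

#' @export
print.conditional_pool <- function(x, ...) {
  cat(sprintf(
    "<conditional_pool> %d bins, %d pooled observations, cwv < %g mm\n",
    nrow(x), sum(x$count), attr(x, "max_cwv")
  ))
  invisible(x)
}

#' Resample precipitation conditionally on counterfactual cwv
#'
#' For each hour, draws a precipitation value uniformly with replacement
#' from the pool of the bin containing that hour's `cwv_t`. An empty (or
#' absent) bin falls back to the nearest non-empty bin at lower cwv; with no
#' pool below, the draw is 0 (the fallback never inflates precipitation).
#' Draws use one independent, seed-derived random stream per cell, so each
#' cell's series is reproducible regardless of cell ordering.
#'
#' @param data Hourly tibble with columns `cell_id` and `cwv_t`.
#' @param pool A [build_pool()] object.
#' @param seed Integer seed.
#' @return `data` with a `p_mc` column (mm/h) appended.
#' @export
mc_resample <- function(data, pool, seed = 1L) {
  stopifnot(inherits(pool, "conditional_pool"))
  if (!all(c("cell_id", "cwv_t") %in% names(data))) {
    stop("`data` must have columns cell_id, cwv_t", call. = FALSE)
  }
  if (nrow(pool) == 0) stop("pool is empty", call. = FALSE)
  bw <- attr(pool, "bin_width")
  # nearest pool at or below each hour's bin (0 draws if none below)
  idx <- findInterval(data$cwv_t, pool$bin_lower)

  p_mc <- numeric(nrow(data))
  for (cell in sort(unique(data$cell_id))) {
    rows <- which(data$cell_id == cell)
    ci <- idx[rows]
    withr::with_seed(derive_seed(seed, 10000L + as.integer(cell)), {
      draws <- numeric(length(rows))
      for (b in unique(ci)) {
        sel <- ci == b
        if (b == 0) next
        vals <- pool$values[[b]]
        draws[sel] <- vals[sample.int(length(vals), sum(sel), replace = TRUE)]
      }
    })
    p_mc[rows] <- draws
  }
  dplyr::mutate(data, p_mc = p_mc)
}

#' Daily summary of the Monte Carlo counterfactual
#'
#' Aggregates the resampled and observed hourly series to daily totals
#' (area-wide mean over cells), filters wet days independently in each
#' series, and reports median event sizes, the event-size percent decrease,
#' and the total precipitation percent decrease. Because resampling destroys
#' sub-daily temporal structure, only daily totals and their distribution
#' are summarised.
#'
#' @param data Hourly tibble with `time`, `cell_id`, `precip` (observed) and
#'   `p_mc` (from [mc_resample()]).
#' @param cutoff Wet-day threshold (mm/day).
#' @return A one-row tibble with `median_event_obs`, `median_event_mc`,
#'   `event_reduction_pct`, `total_reduction_pct`, `n_wet_obs`, `n_wet_mc`.
#' @export
mc_daily_summary <- function(data, cutoff = 0.01) {
  need <- c("time", "cell_id", "precip", "p_mc")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns time, cell_id, precip, p_mc", call. = FALSE)
  }
  daily <- aggregate_precip(data, "daily", cols = c("precip", "p_mc"))
  daily_area <- area_mean(daily)
  obs_wet <- filter_wet_days(daily_area, precip, cutoff)
  mc_wet <- filter_wet_days(daily_area, p_mc, cutoff)
  med_obs <- stats::median(obs_wet$precip)
  med_mc <- if (nrow(mc_wet) > 0) stats::median(mc_wet$p_mc) else 0
  tibble::tibble(
    median_event_obs = med_obs,
    median_event_mc = med_mc,
    event_reduction_pct = 100 * (1 - med_mc / med_obs),
    total_reduction_pct = pct_of_sums(daily_area$precip, daily_area$p_mc),
    n_wet_obs = nrow(obs_wet),
    n_wet_mc = nrow(mc_wet)
  )
}
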