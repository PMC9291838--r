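# Counterfactual construction: remove the transpired share from cwv, rescale
# precipitation by conditional-quartile ratios, aggregate, and summarise
# reductions.

#' Counterfactual column water vapor without the transpired contribution
#'
#' Multiplies each cell's hourly cwv by `1 - f_t` for the calendar month of
#' the timestamp, yielding the water vapor the cell would have held without
#' the tracked transpiration source.
#'
#' @param data Hourly tibble with columns `time`, `cell_id`, `cwv`.
#' @param ft Transpired-fraction tibble with columns `cell_id`, `month`
#'   (1--12), `ft` in `[0, 1]` (e.g. from [simulate_ft()]); every
#'   (cell, month) present in `data` must be covered.
#' @return `data` with columns `ft` and `cwv_t = (1 - ft) * cwv` appended.
#' @export
counterfactual_cwv <- function(data, ft) {
  need <- c("time", "cell_id", "cwv")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns time, cell_id, cwv", call. = FALSE)
  }
  if (any(ft$ft < 0 | ft$ft > 1)) {
    stop("`ft` values must lie in [0, 1]", call. = FALSE)
  }
  out <- dplyr::mutate(data, month = lubridate::month(.data$time))
  out <- dplyr::left_join(out, ft, by = c("cell_id", "month"))
  if (anyNA(out$ft)) {
    miss <- dplyr::distinct(
      dplyr::filter(out, is.na(.data$ft)), .data$cell_id, .data$month
    )
    stop(sprintf(
      "ft missing for %d (cell, month) pairs, e.g. %s",
      nrow(miss),
      paste(utils::head(sprintf("(%d, %d)", miss$cell_id, miss$month), 5),
            collapse = ", ")
    ), call. = FALSE)
  }
  dplyr::mutate(out, cwv_t = (1 - .data$ft) * .data$cwv, month = NULL)
}

#' Quantile-ratio scaling factor
#'
#' For each hour, the factor `f_q` by which precipitation is scaled is the
#' ratio of the conditional quartile evaluated at the counterfactual cwv to
#' the same quartile at the observed cwv. When both quartiles are below
#' `eps` (deep in the dry regime) the ratio is taken as 1; a vanishing
#' denominator with a non-vanishing numerator indicates a non-monotone curve
#' and also yields 1, with a warning.
#'
#' @param curve A [build_quantile_curve()] result.
#' @param cwv,cwv_t Observed and counterfactual cwv (mm), equal length,
#'   `cwv_t <= cwv` elementwise.
#' @param q Quartile, one of 25, 50, 75.
#' @param eps Dry threshold for the 0/0 convention (mm/h).
#' @return Numeric vector of scaling fractions.
#' @export
quantile_ratio <- function(curve, cwv, cwv_t, q = 50, eps = 1e-9) {
  if (length(cwv) != length(cwv_t)) stop("unequal series lengths", call. = FALSE)
  if (any(cwv_t > cwv + 1e-12)) {
    stop("`cwv_t` must not exceed `cwv`", call. = FALSE)
  }
  num <- lookup_quantile(curve, cwv_t, q)
  den <- lookup_quantile(curve, cwv, q)
  fq <- rep(1, length(cwv))
  ok <- den >= eps
  fq[ok] <- num[ok] / den[ok]
  anomal <- !ok & num >= eps
  if (any(anomal)) {
    warning(sprintf(
      "%d hours with vanishing denominator but non-vanishing numerator (non-monotone curve); factor set to 1",
      sum(anomal)
    ), call. = FALSE)
  }
  fq
}

#' Scale hourly precipitation into its counterfactual value
#'
#' Applies `p_t = f_q * p` hour by hour, where `f_q` comes from
#' [quantile_ratio()] on the row's `(cwv, cwv_t)` pair. Dry hours stay dry
#' regardless of the factor.
#'
#' @param data Hourly tibble with columns `precip`, `cwv`, `cwv_t` (see
#'   [counterfactual_cwv()]).
#' @inheritParams quantile_ratio
#' @return `data` with columns `f_<q>` and `p_t_<q>` appended.
#' @export
reduced_precip <- function(data, curve, q = 50, eps = 1e-9) {
  need <- c("precip", "cwv", "cwv_t")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns precip, cwv, cwv_t", call. = FALSE)
  }
  fq <- quantile_ratio(curve, data$cwv, data$cwv_t, q = q, eps = eps)
  data[[paste0("f_", q)]] <- fq
  data[[paste0("p_t_", q)]] <- fq * data$precip
  data
}

#' Build the full hourly counterfactual series
#'
#' Chains [counterfactual_cwv()] and [reduced_precip()] for each requested
#' quartile.
#'
#' @inheritParams counterfactual_cwv
#' @inheritParams quantile_ratio
#' @param quartiles Quartiles to construct (subset of 25, 50, 75).
#' @return Hourly tibble with `cwv_t`, and `f_<q>`, `p_t_<q>` per quartile.
#' @export
counterfactual_series <- function(data, curve, ft, quartiles = c(25, 50, 75),
                                  eps = 1e-9) {
  out <- counterfactual_cwv(data, ft)
  for (q in quartiles) out <- reduced_precip(out, curve, q = q, eps = eps)
  out
}

period_floor <- function(time, period) {
  switch(period,
    daily = lubridate::floor_date(time, "day"),
    monthly = lubridate::floor_date(time, "month"),
    annual = lubridate::floor_date(time, "year")
  )
}

period_hours <- function(period_start, period) {
  switch(period,
    daily = rep(24, length(period_start)),
    monthly = lubridate::days_in_month(period_start) * 24,
    annual = ifelse(lubridate::leap_year(period_start), 8784, 8760)
  )
}

#' Aggregate hourly precipitation fields to period totals
#'
#' Sums hourly rates (mm/h over 1-h steps, i.e. mm) to daily, monthly or
#' annual totals per cell. Periods not fully covered by hourly data (e.g. a
#' trailing partial month) are dropped with a warning.
#'
#' @param data Hourly tibble with `time`, `cell_id` and the columns to sum.
#' @param period One of `"daily"`, `"monthly"`, `"annual"`.
#' @param cols Tidy-selection of columns to sum; defaults to `precip` and
#'   any `p_t_*` columns.
#' @return Tibble with `cell_id`, `period_start` and one total (mm) per
#'   selected column.
#' @seealso [area_mean()] for the area-wide series.
#' @export
aggregate_precip <- function(data, period = c("daily", "monthly", "annual"),
                             cols = NULL) {
  period <- match.arg(period)
  if (nrow(data) == 0) stop("empty series", call. = FALSE)
  cols_quo <- rlang::enquo(cols)
  sel <- if (rlang::quo_is_null(cols_quo)) {
    rlang::expr(c(dplyr::any_of("precip"), dplyr::starts_with("p_t_")))
  } else {
    cols_quo
  }
  out <- data |>
    dplyr::mutate(period_start = period_floor(.data$time, period)) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      dplyr::across(!!sel, sum),
      .by = c("cell_id", "period_start")
    )
  expect <- period_hours(out$period_start, period)
  incomplete <- out$n_hours < expect
  if (any(incomplete)) {
    warning(sprintf(
      "dropping %d incomplete %s period(s)",
      length(unique(out$period_start[incomplete])), period
    ), call. = FALSE)
    out <- out[!incomplete, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no complete period in series", call. = FALSE)
  dplyr::arrange(dplyr::select(out, -"n_hours"), .data$cell_id,
                 .data$period_start)
}

#' Area-wide series from per-cell period totals
#'
#' The area-wide series is the mean over cells of the per-cell totals, one
#' value per period.
#'
#' @param agg Output of [aggregate_precip()].
#' @return Tibble with `period_start` and the cell-mean of each total column.
#' @export
area_mean <- function(agg) {
  agg |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("cell_id"), mean),
      .by = "period_start"
    ) |>
    dplyr::arrange(.data$period_start)
}

#' Keep wet days only
#'
#' Retains days whose precipitation total meets or exceeds the cutoff
#' (default 0.01 mm/day). Event-size statistics are computed on wet days
#' only; the filter is applied independently to the observed and each
#' counterfactual daily series.
#'
#' @param data Daily tibble.
#' @param col Column holding the daily total (unquoted), default `precip`.
#' @param cutoff Wet-day threshold in mm/day (>= 0).
#' @return The wet-day rows of `data`.
#' @export
filter_wet_days <- function(data, col = precip, cutoff = 0.01) {
  if (cutoff < 0) stop("`cutoff` must be >= 0", call. = FALSE)
  dplyr::filter(data, {{ col }} >= cutoff)
}

#' Percent reduction of a counterfactual aggregate relative to observed
#'
#' Computes `100 * (1 - counterfactual / observed)` elementwise. Periods with
#' zero observed total are excluded (returned as `NA`) and counted in a
#' message; an all-zero observed series is an error.
#'
#' @param observed,counterfactual Matched numeric aggregates (mm).
#' @return Numeric vector of percent reductions (`NA` where observed is 0).
#' @export
percent_reduction <- function(observed, counterfactual) {
  if (length(observed) != length(counterfactual)) {
    stop("unequal series lengths", call. = FALSE)
  }
  if (all(observed == 0)) stop("observed aggregate is all zero", call. = FALSE)
  zero <- observed == 0
  if (any(zero)) {
    message(sprintf(
      "excluding %d period(s) with zero observed precipitation", sum(zero)
    ))
  }
  out <- 100 * (1 - counterfactual / observed)
  out[zero] <- NA_real_
  out
}

pct_of_sums <- function(obs, cf) 100 * (1 - sum(cf) / sum(obs))

#' Summarise observed versus counterfactual precipitation reductions
#'
#' Aggregates an hourly counterfactual series (from
#' [counterfactual_series()]) to daily, monthly and annual totals and
#' derives the headline statistics: median and mean annual percent reduction
#' across cell-years, median monthly reduction across cell-months, absolute
#' annual decrease, wet-day median event sizes with their percent decrease,
#' and the mean cwv reduction for comparison.
#'
#' @param data Hourly tibble with `time`, `cell_id`, `cwv`, `cwv_t`,
#'   `precip` and `p_t_<q>` columns.
#' @param quartiles Quartiles present in `data` (default 25, 50, 75).
#' @param cutoff Wet-day threshold (mm/day) for event statistics.
#' @return A list of class `reduction_summary` with tibbles `daily`
#'   (per cell), `daily_area`, `monthly` (per cell, with per-quartile
#'   reductions), `annual` (likewise), `events` (wet-day medians and percent
#'   decrease per quartile), and `headline` (one row per quartile). The
#'   element `cwv_reduction_pct` holds `100 * (1 - sum(cwv_t)/sum(cwv))`.
#' @export
reduction_summary <- function(data, quartiles = c(25, 50, 75), cutoff = 0.01) {
  pt_cols <- paste0("p_t_", quartiles)
  need <- c("time", "cell_id", "cwv", "cwv_t", "precip", pt_cols)
  if (!all(need %in% names(data))) {
    stop(sprintf("`data` lacks columns: %s",
                 paste(setdiff(need, names(data)), collapse = ", ")),
         call. = FALSE)
  }

  daily <- aggregate_precip(data, "daily")
  monthly <- aggregate_precip(data, "monthly")
  annual <- aggregate_precip(data, "annual")
  daily_area <- area_mean(daily)

  add_reductions <- function(agg) {
    for (q in quartiles) {
      agg[[paste0("red_", q)]] <-
        suppressMessages(percent_reduction(agg$precip, agg[[paste0("p_t_", q)]]))
    }
    agg
  }
  monthly <- add_reductions(monthly)
  annual <- add_reductions(annual)
  n_zero <- sum(monthly$precip == 0) + sum(annual$precip == 0)
  if (n_zero > 0) {
    message(sprintf(
      "excluded %d period(s) with zero observed precipitation from percent-reduction statistics",
      n_zero
    ))
  }

  events <- purrr::map_dfr(quartiles, function(q) {
    obs_wet <- filter_wet_days(daily_area, .data$precip, cutoff)
    cf_wet <- dplyr::filter(daily_area, .data[[paste0("p_t_", q)]] >= cutoff)
    med_obs <- stats::median(obs_wet$precip)
    med_cf <- if (nrow(cf_wet) > 0) {
      stats::median(cf_wet[[paste0("p_t_", q)]])
    } else {
      0
    }
    tibble::tibble(
      q = q,
      n_wet_obs = nrow(obs_wet), n_wet_cf = nrow(cf_wet),
      median_event_obs = med_obs, median_event_cf = med_cf,
      event_reduction_pct = 100 * (1 - med_cf / med_obs)
    )
  })

  headline <- purrr::map_dfr(quartiles, function(q) {
    red_a <- annual[[paste0("red_", q)]]
    red_m <- monthly[[paste0("red_", q)]]
    dec <- annual$precip - annual[[paste0("p_t_", q)]]
    tibble::tibble(
      q = q,
      annual_reduction_median = stats::median(red_a, na.rm = TRUE),
      annual_reduction_mean = mean(red_a, na.rm = TRUE),
      annual_reduction_total = pct_of_sums(annual$precip,
                                           annual[[paste0("p_t_", q)]]),
      annual_decrease_mm = mean(dec),
      monthly_reduction_median = stats::median(red_m, na.rm = TRUE)
    )
  })

  structure(
    list(
      daily = daily, daily_area = daily_area, monthly = monthly,
      annual = annual, events = events, headline = headline,
      cwv_reduction_pct = pct_of_sums(data$cwv, data$cwv_t),
      quartiles = quartiles, cutoff = cutoff
    ),
    class = "reduction_summary"
  )
}

#' @export
print.reduction_summary <- function(x, ...) {
  cat("<reduction_summary>\n")
  cat(sprintf("  cwv reduction: %.1f%%\n", x$cwv_reduction_pct))
  for (i in seq_len(nrow(x$headline))) {
    h <- x$headline[i, ]
    cat(sprintf(
      "  q = %d: annual reduction %.1f%% (median over cell-years), %.1f mm/yr; monthly median %.1f%%\n",
      h$q, h$annual_reduction_median, h$annual_decrease_mm,
      h$monthly_reduction_median
    ))
  }
  invisible(x)
}

#' @export
tidy.reduction_summary <- function(x, ...) {
  dplyr::left_join(x$headline, x$events, by = "q")
}

#' @export
glance.reduction_summary <- function(x, ...) {
  h50 <- x$headline[x$headline$q == 50, ]
  e50 <- x$events[x$events$q == 50, ]
  tibble::tibble(
    cwv_reduction_pct = x$cwv_reduction_pct,
    annual_reduction_median_q50 = if (nrow(h50)) h50$annual_reduction_median else NA_real_,
    event_reduction_pct_q50 = if (nrow(e50)) e50$event_reduction_pct else NA_real_,
    n_cells = length(unique(x$annual$cell_id)),
    n_cell_years = nrow(x$annual)
  )
}
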