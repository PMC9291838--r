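# Summary diagnostics: seasonal cycle of the reduction, spatial profiles,
# mean transpired fraction, and the post-rainfall cwv-change check.

#' Seasonal cycle of the precipitation reduction
#'
#' Pools the per-(cell, month) percent reductions of a [reduction_summary()]
#' by calendar month. The central line is the median (over cells and years)
#' of the reduction computed from the median-quartile series (q = 50); the
#' band spans the reductions from the lower and upper quartile series
#' (q = 25 gives the upper edge, q = 75 the lower, since scaling by the
#' steeper lower-quartile curve removes more precipitation).
#'
#' @param summary A [reduction_summary()] computed with quartiles 25, 50, 75.
#' @return A 12-row tibble of class `seasonal_profile`: `month`,
#'   `reduction_median`, `reduction_lower`, `reduction_upper` (percent).
#' @export
seasonal_cycle <- function(summary) {
  stopifnot(inherits(summary, "reduction_summary"))
  if (!all(c(25, 50, 75) %in% summary$quartiles)) {
    stop("seasonal cycle needs quartiles 25, 50 and 75", call. = FALSE)
  }
  m <- dplyr::mutate(summary$monthly,
                     month = lubridate::month(.data$period_start))
  if (!all(1:12 %in% m$month)) {
    stop("need at least one complete year (all 12 calendar months)",
         call. = FALSE)
  }
  out <- m |>
    dplyr::summarise(
      reduction_median = stats::median(.data$red_50, na.rm = TRUE),
      reduction_lower = stats::median(.data$red_75, na.rm = TRUE),
      reduction_upper = stats::median(.data$red_25, na.rm = TRUE),
      .by = "month"
    ) |>
    dplyr::arrange(.data$month)
  structure(out, class = c("seasonal_profile", class(out)))
}

#' Spatial profile of the annual precipitation reduction
#'
#' Averages per-cell annual reductions along one axis of the grid: per
#' longitude column (`axis = "longitude"`) or latitude row
#' (`axis = "latitude"`). Reported both in percent (mean over cell-years of
#' the q = 50 reduction) and as the absolute decrease in mm/year.
#'
#' @param summary A [reduction_summary()].
#' @param grid The [make_grid()] grid the series was computed on.
#' @param axis `"longitude"` or `"latitude"`.
#' @return A tibble of class `spatial_profile` with columns `coord` (deg),
#'   `mean_reduction_pct`, `mean_decrease_mm`, `n_cells`.
#' @export
spatial_profile <- function(summary, grid,
                            axis = c("longitude", "latitude")) {
  stopifnot(inherits(summary, "reduction_summary"),
            inherits(grid, "pickup_grid"))
  axis <- match.arg(axis)
  coord_col <- if (axis == "longitude") "lon" else "lat"
  cell <- summary$annual |>
    dplyr::summarise(
      reduction_pct = mean(.data$red_50, na.rm = TRUE),
      decrease_mm = mean(.data$precip - .data$p_t_50),
      .by = "cell_id"
    ) |>
    dplyr::left_join(tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")],
                     by = "cell_id")
  out <- cell |>
    dplyr::summarise(
      mean_reduction_pct = mean(.data$reduction_pct, na.rm = TRUE),
      mean_decrease_mm = mean(.data$decrease_mm),
      n_cells = dplyr::n(),
      .by = dplyr::all_of(coord_col)
    ) |>
    dplyr::rename(coord = dplyr::all_of(coord_col)) |>
    dplyr::arrange(.data$coord)
  structure(out, class = c("spatial_profile", class(out)), axis = axis)
}

#' Mean transpired fraction, in percent
#'
#' `100 *` the mean of `f_t` over all (cell, month) values -- the average
#' share of column water vapor attributed to the tracked transpiration
#' source.
#'
#' @param ft Tibble with an `ft` column (e.g. from [simulate_ft()]).
#' @return A single percentage.
#' @export
mean_transpired_fraction <- function(ft) {
  if (!"ft" %in% names(ft)) stop("`ft` must have an `ft` column", call. = FALSE)
  if (any(ft$ft < 0 | ft$ft > 1)) {
    stop("`ft` values must lie in [0, 1]", call. = FALSE)
  }
  100 * mean(ft$ft)
}

#' Change in column water vapor around rainfall events
#'
#' Checks whether cwv drops after rainfall: for each event hour
#' (`precip >= event_threshold`, events kept greedily with at least
#' `min_separation` hours between them and full windows inside the series),
#' computes `delta = mean(cwv over the post window) - mean(cwv over the pre
#' window)`. A mean delta near zero supports treating the hourly cwv series
#' as unaffected by individual rain events when constructing
#' counterfactuals.
#'
#' @param data Hourly tibble with `time`, `cell_id`, `cwv`, `precip`.
#' @param event_threshold Event definition, mm/h (default 1).
#' @param window Pre/post window length in hours (default 3).
#' @param min_separation Minimum hours between retained events (default 6).
#' @param n_boot Bootstrap replicates for the mean-delta interval.
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `cwv_event_check`: `deltas` (tibble `cell_id`,
#'   `time`, `delta` in mm) and `summary` (one row: `n_events`,
#'   `mean_delta`, `ci_lower`, `ci_upper`, 95% bootstrap interval). With no
#'   qualifying events, `deltas` is empty and a warning is raised.
#' @export
post_event_cwv_change <- function(data, event_threshold = 1, window = 3,
                                  min_separation = 6, n_boot = 1000,
                                  seed = 1L) {
  need <- c("time", "cell_id", "cwv", "precip")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns time, cell_id, cwv, precip", call. = FALSE)
  }
  if (window < 1) stop("`window` must be >= 1 hour", call. = FALSE)

  one_cell <- function(d) {
    d <- dplyr::arrange(d, .data$time)
    n <- nrow(d)
    cand <- which(d$precip >= event_threshold)
    cand <- cand[cand > window & cand <= n - window]
    kept <- integer(0)
    last <- -Inf
    for (i in cand) {
      if (i - last >= min_separation) {
        kept <- c(kept, i)
        last <- i
      }
    }
    if (length(kept) == 0) return(NULL)
    delta <- vapply(kept, function(i) {
      mean(d$cwv[(i + 1):(i + window)]) - mean(d$cwv[(i - window):(i - 1)])
    }, numeric(1))
    tibble::tibble(cell_id = d$cell_id[kept], time = d$time[kept],
                   delta = delta)
  }

  deltas <- data |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(one_cell) |>
    purrr::compact() |>
    purrr::list_rbind()

  if (is.null(deltas) || nrow(deltas) == 0) {
    warning("no qualifying rainfall events found", call. = FALSE)
    deltas <- tibble::tibble(cell_id = integer(0),
                             time = as.POSIXct(character(0), tz = "UTC"),
                             delta = numeric(0))
    summ <- tibble::tibble(n_events = 0L, mean_delta = NA_real_,
                           ci_lower = NA_real_, ci_upper = NA_real_)
  } else {
    boot_means <- withr::with_seed(derive_seed(seed, 4L), {
      vapply(seq_len(n_boot), function(i) {
        mean(sample(deltas$delta, nrow(deltas), replace = TRUE))
      }, numeric(1))
    })
    summ <- tibble::tibble(
      n_events = nrow(deltas),
      mean_delta = mean(deltas$delta),
      ci_lower = stats::quantile(boot_means, 0.025, names = FALSE),
      ci_upper = stats::quantile(boot_means, 0.975, names = FALSE)
    )
  }
  structure(list(deltas = deltas, summary = summ),
            class = "cwv_event_check")
}

#' @export
print.cwv_event_check <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cwv_event_check> %d events; mean post-pre cwv change %.3f mm (95%% CI %.3f to %.3f)\n",
    s$n_events, s$mean_delta, s$ci_lower, s$ci_upper
  ))
  invisible(x)
}

#' Plot the seasonal cycle of the reduction
#'
#' @param object A [reduction_summary()].
#' @param ... Unused.
#' @return A ggplot object: monthly percent reduction (median line,
#'   interquartile band from the q = 25 / q = 75 series).
#' @export
autoplot.reduction_summary <- function(object, ...) {
  sc <- seasonal_cycle(object)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$reduction_lower,
                   ymax = .data$reduction_upper),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reduction_median),
                       linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = "precipitation reduction (%)",
                  title = "Monthly percent reduction in precipitation")
}

#' Plot a spatial profile of the reduction
#'
#' @param profile A [spatial_profile()].
#' @return A ggplot object.
#' @export
plot_spatial_profile <- function(profile) {
  stopifnot(inherits(profile, "spatial_profile"))
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$coord,
                               y = .data$mean_reduction_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (deg)", attr(profile, "axis")),
      y = "mean annual reduction (%)",
      title = sprintf("Annual precipitation reduction by %s",
                      attr(profile, "axis"))
    )
}
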