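# Text I/O for gridded fields and curves: long-format CSV with a units
# header line (time/lat/lon mandatory), round-tripping values bit-exactly.

format_units <- function(units) {
  paste0("# units: ", paste(names(units), unname(units), sep = "=",
                            collapse = ";"))
}

parse_units <- function(line) {
  body <- sub("^#\\s*units:\\s*", "", line)
  parts <- strsplit(body, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, function(x) trimws(x[2]), character(1)),
    vapply(kv, function(x) trimws(x[1]), character(1))
  )
}

canonical_unit <- function(u) {
  u <- trimws(u)
  # 1 kg of water per m^2 is a 1 mm column
  if (u %in% c("kg m-2", "kg/m2", "kg m**-2")) return("mm")
  if (u %in% c("mm/h", "mm hr-1", "mm h**-1")) return("mm h-1")
  u
}

accepted_units <- c(cwv = "mm", precip = "mm h-1", ft = "1",
                    cwv_t = "mm", p_mc = "mm h-1")

#' Write and read gridded fields as long-format CSV
#'
#' Gridded series are stored as plain-text long tables: mandatory dimension
#' columns `time` (ISO 8601 UTC), `lat`, `lon` (degrees), one column per
#' variable, and a leading `# units:` header declaring each variable's
#' units. Values round-trip bit-exactly. On read, the dimension columns and
#' units declarations are validated; for water columns, `kg m-2` is accepted
#' as equivalent to `mm`.
#'
#' @param data Tibble with `time` plus either `lat`/`lon` or `cell_id` (in
#'   which case `grid` supplies the coordinates).
#' @param path Output/input file path.
#' @param units Named character vector of units per variable column;
#'   defaults cover `cwv` (mm), `precip` (mm h-1), `ft` (1).
#' @param grid Optional [make_grid()] grid to translate `cell_id` into
#'   coordinates on write and back on read.
#' @return `read_gridded()` returns the tibble (with `cell_id` restored if
#'   `grid` is given); `write_gridded()` returns `path` invisibly.
#' @export
write_gridded <- function(data, path, units = NULL, grid = NULL) {
  if (!"time" %in% names(data)) {
    stop("`data` must have a `time` column", call. = FALSE)
  }
  if (!all(c("lat", "lon") %in% names(data))) {
    if (is.null(grid) || !"cell_id" %in% names(data)) {
      stop("`data` needs lat/lon columns, or cell_id plus `grid`",
           call. = FALSE)
    }
    data <- dplyr::left_join(
      data, tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")],
      by = "cell_id"
    )
    data$cell_id <- NULL
  }
  vars <- setdiff(names(data), c("time", "lat", "lon"))
  if (is.null(units)) {
    units <- accepted_units[intersect(names(accepted_units), vars)]
  }
  missing_units <- setdiff(vars, names(units))
  if (length(missing_units) > 0) {
    stop(sprintf("no units declared for: %s",
                 paste(missing_units, collapse = ", ")), call. = FALSE)
  }
  data <- dplyr::select(data, "time", "lat", "lon", dplyr::all_of(vars))
  # %.17g guarantees bit-exact double round-trips through text
  data <- dplyr::mutate(
    data,
    dplyr::across(dplyr::all_of(vars) & dplyr::where(is.double),
                  ~ sprintf("%.17g", .x))
  )
  writeLines(format_units(units[vars]), path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_gridded
#' @export
read_gridded <- function(path, grid = NULL) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#\\s*units:", header)) {
    stop("file lacks the `# units:` header line", call. = FALSE)
  }
  units <- parse_units(header)
  # base parser: strtod() is correctly rounded, so doubles round-trip exactly
  data <- tibble::as_tibble(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  )
  if ("time" %in% names(data) && is.character(data$time)) {
    parsed <- lubridate::ymd_hms(data$time, tz = "UTC", quiet = TRUE)
    if (!anyNA(parsed)) data$time <- parsed
  }
  for (dim in c("time", "lat", "lon")) {
    if (!dim %in% names(data)) {
      stop(sprintf("missing required dimension column `%s`", dim),
           call. = FALSE)
    }
  }
  if (!inherits(data$time, "POSIXct")) {
    stop("`time` column is not a parseable datetime", call. = FALSE)
  }
  vars <- setdiff(names(data), c("time", "lat", "lon"))
  for (v in vars) {
    if (!v %in% names(units)) {
      stop(sprintf("no units declared for variable `%s`", v), call. = FALSE)
    }
    u <- canonical_unit(units[[v]])
    if (v %in% names(accepted_units) && u != accepted_units[[v]]) {
      stop(sprintf("variable `%s` has units `%s`, expected `%s`",
                   v, units[[v]], accepted_units[[v]]), call. = FALSE)
    }
  }
  if (!is.null(grid)) {
    gt <- tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")]
    data <- dplyr::left_join(data, gt, by = c("lat", "lon"))
    if (anyNA(data$cell_id)) {
      stop("coordinates in file do not match the supplied grid",
           call. = FALSE)
    }
    data <- dplyr::select(data, "time", "cell_id",
                          dplyr::all_of(vars))
  }
  data
}

#' Serialize a quantile curve to CSV or JSON
#'
#' CSV columns are `bin_lower_mm`, `count`, `p25`, `p50`, `p75`, `valid`,
#' with the binning parameters in a leading comment line; JSON carries the
#' same fields plus the parameters.
#'
#' @param curve A [build_quantile_curve()] result.
#' @param path Output/input file path (`.csv` or `.json`; format inferred
#'   from the extension).
#' @return `read_quantile_curve()` returns the restored `quantile_curve`;
#'   `write_quantile_curve()` returns `path` invisibly.
#' @export
write_quantile_curve <- function(curve, path) {
  stopifnot(inherits(curve, "quantile_curve"))
  pars <- list(bin_width = attr(curve, "bin_width"),
               min_count = attr(curve, "min_count"),
               max_cwv = attr(curve, "max_cwv"))
  tab <- tibble::as_tibble(curve)
  names(tab)[names(tab) == "bin_lower"] <- "bin_lower_mm"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(params = pars, bins = tab), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("# bin_width=%g;min_count=%g;max_cwv=%g",
                       pars$bin_width, pars$min_count, pars$max_cwv), path)
    readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  }
  invisible(path)
}

#' @rdname write_quantile_curve
#' @export
read_quantile_curve <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- tibble::as_tibble(obj$bins)
    pars <- obj$params
  } else {
    header <- readLines(path, n = 1L)
    kv <- parse_units(sub("^#\\s*", "# units: ", header))
    pars <- lapply(kv, as.numeric)
    tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  }
  names(tab)[names(tab) == "bin_lower_mm"] <- "bin_lower"
  tab$valid <- as.logical(tab$valid)
  structure(tab,
    class = c("quantile_curve", class(tab)),
    bin_width = pars$bin_width, min_count = pars$min_count,
    max_cwv = pars$max_cwv
  )
}
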