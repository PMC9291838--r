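#' Construct a regular latitude--longitude analysis grid
#'
#' Builds the regular grid of cell centers covering a rectangular study box.
#' Cell centers are offset by `resolution / 2` from the box edges and ordered
#' row-major: latitude varies slowest (south to north), longitude fastest
#' (west to east). Latitudes are negative southward and longitudes negative
#' westward, so the classic southern-Amazon study box (0--18 deg S,
#' 65--50 deg W) is `make_grid(-18, 0, -65, -50, 0.25)` and has 4320 cells.
#'
#' @param south,north Southern and northern box edges, decimal degrees
#'   (`north > south`).
#' @param west,east Western and eastern box edges, decimal degrees
#'   (`east > west`).
#' @param resolution Grid spacing in degrees (> 0). Both box dimensions must
#'   be integer multiples of it.
#'
#' @return A tibble of class `pickup_grid` with one row per cell and columns
#'   `cell_id` (integer, row-major order), `lat`, `lon` (cell centers,
#'   degrees). Attributes `south`, `north`, `west`, `east`, `resolution`,
#'   `nlat`, `nlon` record the box.
#' @examples
#' grid <- make_grid(-18, 0, -65, -50, 0.25)
#' nrow(grid) # 4320
#' @export
make_grid <- function(south, north, west, east, resolution) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L)
  if (resolution <= 0) stop("`resolution` must be positive", call. = FALSE)
  if (!(north > south)) stop("`north` must exceed `south`", call. = FALSE)
  if (!(east > west)) stop("`east` must exceed `west`", call. = FALSE)

  n_exact <- function(span) span / resolution
  check_div <- function(span, what) {
    n <- n_exact(span)
    if (abs(n - round(n)) > 1e-9 * max(1, abs(n))) {
      stop(sprintf(
        "%s extent (%g deg) is not divisible by resolution %g deg",
        what, span, resolution
      ), call. = FALSE)
    }
    as.integer(round(n))
  }
  nlat <- check_div(north - south, "latitude")
  nlon <- check_div(east - west, "longitude")

  lat <- south + resolution * (seq_len(nlat) - 0.5)
  lon <- west + resolution * (seq_len(nlon) - 0.5)
  out <- tibble::tibble(
    cell_id = seq_len(nlat * nlon),
    lat = rep(lat, each = nlon),
    lon = rep(lon, times = nlat)
  )
  structure(out,
    class = c("pickup_grid", class(out)),
    south = south, north = north, west = west, east = east,
    resolution = resolution, nlat = nlat, nlon = nlon
  )
}

#' @export
print.pickup_grid <- function(x, ...) {
  cat(sprintf(
    "<pickup_grid> %d cells (%d lat x %d lon) at %g deg, lat [%g, %g], lon [%g, %g]\n",
    nrow(x), attr(x, "nlat"), attr(x, "nlon"), attr(x, "resolution"),
    attr(x, "south"), attr(x, "north"), attr(x, "west"), attr(x, "east")
  ))
  NextMethod()
}
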