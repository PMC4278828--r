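#' Grid geometry: the georeferencing of a regular raster
#'
#' All rasters in the package live on a regular grid of square cells.
#' Row 1 is the northern edge; cell centres are at
#' `x = x_origin + (col - 0.5) * cell_size` and
#' `y = y_origin - (row - 0.5) * cell_size`. A point belongs to the cell
#' whose half-open interval `[edge, edge + cell_size)` contains it.
#'
#' @param n_rows,n_cols positive integers.
#' @param x_origin,y_origin west edge and north edge, in map units.
#' @param cell_size cell edge length in map units (> 0; cells are square).
#' @param crs_kind `"projected_metric"` (map units are metres) or
#'   `"geographic_degrees"` (map units are decimal degrees).
#' @return An object of class `grid_geometry`.
#' @examples
#' grid_geometry(100, 100, 0, 1e5, 1000, "projected_metric")
#' @export
grid_geometry <- function(n_rows, n_cols, x_origin, y_origin, cell_size,
                          crs_kind = c("projected_metric", "geographic_degrees")) {
  crs_kind <- match.arg(crs_kind)
  if (!is.numeric(n_rows) || n_rows < 1 || n_rows != round(n_rows))
    stop("n_rows must be a positive integer")
  if (!is.numeric(n_cols) || n_cols < 1 || n_cols != round(n_cols))
    stop("n_cols must be a positive integer")
  if (!is.numeric(cell_size) || !is.finite(cell_size) || cell_size <= 0)
    stop("unsupported geometry: cell_size must be > 0")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
    cell_size = as.numeric(cell_size), crs_kind = crs_kind
  ), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells, cell %g, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin,
              x$crs_kind))
  invisible(x)
}

#' Test whether two grid geometries are aligned
#'
#' Aligned means every field equal (within a tiny numeric tolerance on the
#' real-valued fields); only aligned layers may be combined cell-wise.
#'
#' @param a,b `grid_geometry` objects.
#' @return `TRUE` or `FALSE`.
#' @export
geometry_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  tol <- 1e-9 * max(1, abs(a$cell_size))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$crs_kind == b$crs_kind
}

#' Cell-centre coordinates of every cell
#'
#' @param geom a `grid_geometry`.
#' @return A list with vectors `x` (length `n_cols`, west to east) and `y`
#'   (length `n_rows`, north to south).
#' @export
cell_centers <- function(geom) {
  list(x = geom$x_origin + (seq_len(geom$n_cols) - 0.5) * geom$cell_size,
       y = geom$y_origin - (seq_len(geom$n_rows) - 0.5) * geom$cell_size)
}

#' Map coordinates to (row, col) indices
#'
#' Points outside the extent get `NA` indices. Ownership is half-open:
#' a point exactly on the shared edge of two cells belongs to the
#' east/south one, except on the outer north/west boundary.
#'
#' @param geom a `grid_geometry`.
#' @param x,y numeric vectors of map coordinates.
#' @return A list of integer vectors `row` and `col`.
#' @export
point_to_cell <- function(geom, x, y) {
  col <- floor((x - geom$x_origin) / geom$cell_size) + 1
  row <- floor((geom$y_origin - y) / geom$cell_size) + 1
  # the north and west outer edges belong to row/col 1
  row[geom$y_origin - y == 0] <- 1L
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > geom$n_cols | row < 1 | row > geom$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Convert kilometres to map units
#'
#' On projected metric grids a kilometre is 1000 map units. On geographic
#' grids one degree of latitude is taken as 111.19 km (spherical Earth,
#' radius 6371 km); the caller applies the `cos(latitude)` factor for the
#' east-west axis. The 10-minute grid cells typical of bird-atlas data are
#' about 18.5 km across under this constant.
#'
#' @param distance_km distance in kilometres (vectorised).
#' @param latitude latitude in degrees, `|latitude| < 90`. Ignored for
#'   projected grids and for the latitude axis; exposed so callers convert
#'   per point.
#' @param crs_kind `"projected_metric"` or `"geographic_degrees"`.
#' @return Distance in map units (metres or degrees of latitude).
#' @examples
#' km_to_map_units(10, 0, "projected_metric")      # 10000 m
#' km_to_map_units(111.19, -42, "geographic_degrees") # 1 degree
#' @export
km_to_map_units <- function(distance_km, latitude = 0,
                            crs_kind = c("projected_metric", "geographic_degrees")) {
  crs_kind <- match.arg(crs_kind)
  stopifnot(all(abs(latitude) < 90))
  if (crs_kind == "projected_metric") distance_km * 1000
  else distance_km / 111.19
}

# km per degree of latitude used throughout (2 * pi * 6371 / 360 ~ 111.19)
KM_PER_DEGREE <- 111.19
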