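#' A single raster layer
#'
#' A `grid_layer` couples a [grid_geometry()] with an `n_rows x n_cols`
#' numeric matrix of cell values. Nodata cells are stored as `NA` and are
#' excluded from all statistics; every finite value is, by construction,
#' an unmasked cell.
#'
#' @param geometry a `grid_geometry`.
#' @param values numeric matrix (`n_rows x n_cols`, row 1 = north) or a
#'   single number recycled to the full grid. `NA` marks nodata.
#' @return An object of class `grid_layer`.
#' @examples
#' g <- grid_layer(grid_geometry(2, 3, 0, 2000, 1000), 1.5)
#' grid_values(g)
#' @export
grid_layer <- function(geometry, values) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), geometry$n_rows, geometry$n_cols)
  if (!is.matrix(values) || nrow(values) != geometry$n_rows ||
      ncol(values) != geometry$n_cols)
    stop("values must be an n_rows x n_cols matrix")
  storage.mode(values) <- "double"
  values[!is.finite(values)] <- NA_real_
  structure(list(geometry = geometry, values = values), class = "grid_layer")
}

#' @rdname grid_layer
#' @param grid a `grid_layer`.
#' @export
grid_values <- function(grid) grid$values

#' @rdname grid_layer
#' @export
grid_mask <- function(grid) is.na(grid$values)

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_layer> %d x %d, %d nodata cells",
              x$geometry$n_rows, x$geometry$n_cols, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

# Values at point locations (cell containing each point); NA outside extent
# or on nodata cells.
extract_at_points <- function(grid, x, y) {
  idx <- point_to_cell(grid$geometry, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

grids_equal <- function(a, b, tol = 0) {
  if (!geometry_aligned(a$geometry, b$geometry)) return(FALSE)
  ma <- is.na(a$values); mb <- is.na(b$values)
  if (!identical(ma, mb)) return(FALSE)
  if (all(ma)) return(TRUE)
  max(abs(a$values[!ma] - b$values[!mb])) <= tol
}
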