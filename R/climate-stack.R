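#' Monthly climate stack
#'
#' A `climate_stack` holds 36 aligned monthly layers — 12 months each of
#' minimum temperature (degrees C), maximum temperature (degrees C) and
#' precipitation (mm) — for one period or scenario. A cell masked in any
#' layer is masked in all (the mask is harmonised at construction);
#' `tmax >= tmin` and `prec >= 0` must hold cell-wise.
#'
#' @param geometry a `grid_geometry`.
#' @param tmin,tmax,prec numeric arrays of dimension
#'   `c(n_rows, n_cols, 12)` (`NA` = nodata).
#' @param period_label free-text label for the period or scenario.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(geometry, tmin, tmax, prec, period_label = "current") {
  stopifnot(inherits(geometry, "grid_geometry"))
  dims <- c(geometry$n_rows, geometry$n_cols, 12L)
  for (nm in c("tmin", "tmax", "prec")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), dims) && !identical(as.integer(dim(a)), dims))
      stop(nm, " must be an n_rows x n_cols x 12 array")
  }
  storage.mode(tmin) <- "double"; storage.mode(tmax) <- "double"
  storage.mode(prec) <- "double"
  # harmonise masks across all 36 layers
  mask <- is.na(tmin[, , 1])
  for (m in 1:12)
    mask <- mask | is.na(tmin[, , m]) | is.na(tmax[, , m]) | is.na(prec[, , m])
  for (m in 1:12) {
    tmin[, , m][mask] <- NA_real_
    tmax[, , m][mask] <- NA_real_
    prec[, , m][mask] <- NA_real_
  }
  ok <- !mask
  if (any(tmax[rep(ok, 12)] < tmin[rep(ok, 12)], na.rm = TRUE))
    stop("invalid climate stack: tmax < tmin at some cells")
  if (any(prec[rep(ok, 12)] < 0, na.rm = TRUE))
    stop("invalid climate stack: negative precipitation")
  structure(list(geometry = geometry, tmin = tmin, tmax = tmax, prec = prec,
                 period_label = period_label, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> '%s': %d x %d cells, %d nodata; tmean %.1f C, annual prec %.0f mm\n",
              x$period_label, x$geometry$n_rows, x$geometry$n_cols,
              sum(x$mask),
              mean((x$tmin + x$tmax) / 2, na.rm = TRUE),
              mean(apply(x$prec, c(1, 2), sum), na.rm = TRUE)))
  invisible(x)
}

#' Future-climate anomaly ("delta") stack
#'
#' Anomalies of one global climate model (GCM) under one emissions
#' scenario relative to the baseline period. Temperature deltas are
#' additive (degrees C); precipitation deltas are either additive (mm) or
#' relative (unitless ratios, `>= 0`), declared by `precip_mode`.
#'
#' @inheritParams climate_stack
#' @param gcm_id text identifier of the climate model.
#' @param scenario_id emissions scenario label (e.g. `"A2"`, `"B1"`).
#' @param target_year centre year of the future period.
#' @param precip_mode `"relative"` or `"additive"`.
#' @return An object of class `delta_stack`.
#' @export
delta_stack <- function(geometry, tmin, tmax, prec, gcm_id,
                        scenario_id = "custom", target_year = 2085L,
                        precip_mode = c("relative", "additive")) {
  precip_mode <- match.arg(precip_mode)
  dims <- c(geometry$n_rows, geometry$n_cols, 12L)
  for (nm in c("tmin", "tmax", "prec")) {
    a <- get(nm)
    if (!is.array(a) || !identical(as.integer(dim(a)), dims))
      stop(nm, " must be an n_rows x n_cols x 12 array")
  }
  if (precip_mode == "relative" && any(prec < 0, na.rm = TRUE))
    stop("relative precipitation deltas must be >= 0")
  structure(list(geometry = geometry, tmin = tmin, tmax = tmax, prec = prec,
                 gcm_id = gcm_id, scenario_id = scenario_id,
                 target_year = as.integer(target_year),
                 precip_mode = precip_mode),
            class = "delta_stack")
}

#' @export
print.delta_stack <- function(x, ...) {
  cat(sprintf("<delta_stack> %s / %s (%d): mean warming %+.2f C, precip %s %.3g\n",
              x$gcm_id, x$scenario_id, x$target_year,
              mean((x$tmin + x$tmax) / 2, na.rm = TRUE), x$precip_mode,
              mean(x$prec, na.rm = TRUE)))
  invisible(x)
}

# one monthly layer as a grid_layer
stack_layer <- function(stack, var, month) {
  grid_layer(stack$geometry, stack[[var]][, , month])
}

#' Read or write a climate stack as 36 raster files
#'
#' Layers are discovered under `dir` by the filename template
#' `{var}_{month}` with `var` one of `tmin`, `tmax`, `prec` and a
#' two-digit month, e.g. `tmin_01.asc`. `prefix` prepends e.g. `se_` for
#' error-surface sets.
#'
#' @param dir directory containing (or to receive) the 36 rasters.
#' @param format raster format passed to [read_raster()]/[write_raster()].
#' @param crs_kind CRS kind assumed for ASCII rasters.
#' @param prefix filename prefix before the variable name.
#' @param period_label label for the returned stack.
#' @return `read_climate_stack()` returns a `climate_stack`.
#' @export
read_climate_stack <- function(dir, format = "esri_ascii",
                               crs_kind = "projected_metric", prefix = "",
                               period_label = basename(dir)) {
  raw <- read_var_arrays(dir, format, crs_kind, prefix)
  climate_stack(raw$geometry, raw$tmin, raw$tmax, raw$prec, period_label)
}

# 36 rasters -> geometry + three 12-month arrays, without stack validation
read_var_arrays <- function(dir, format, crs_kind, prefix = "") {
  ext <- if (format == "geotiff") "tif" else "asc"
  arrs <- list()
  geom <- NULL
  for (var in c("tmin", "tmax", "prec")) {
    a <- NULL
    for (m in 1:12) {
      p <- file.path(dir, sprintf("%s%s_%02d.%s", prefix, var, m, ext))
      g <- read_raster(p, format, crs_kind)
      if (is.null(geom)) geom <- g$geometry
      else if (!geometry_aligned(geom, g$geometry))
        stop("layer ", basename(p), " is not aligned with the rest of the stack")
      if (is.null(a)) a <- array(NA_real_, c(geom$n_rows, geom$n_cols, 12))
      a[, , m] <- g$values
    }
    arrs[[var]] <- a
  }
  c(list(geometry = geom), arrs)
}

#' @rdname read_climate_stack
#' @param stack a `climate_stack`.
#' @export
write_climate_stack <- function(stack, dir, format = "esri_ascii", prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "geotiff") "tif" else "asc"
  for (var in c("tmin", "tmax", "prec"))
    for (m in 1:12)
      write_raster(stack_layer(stack, var, m),
                   file.path(dir, sprintf("%s%s_%02d.%s", prefix, var, m, ext)),
                   format)
  invisible(dir)
}
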