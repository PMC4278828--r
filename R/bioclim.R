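#' Derive the six bioclimatic predictors from a monthly climate stack
#'
#' Computes, per cell, the six summaries of climate used as model
#' predictors: annual mean temperature, minimum temperature of the
#' coldest month, maximum temperature of the warmest month, annual
#' precipitation, and precipitation of the warmest and of the coldest
#' quarter.
#'
#' Monthly mean temperature is `(tmin + tmax) / 2`. A "quarter" is any of
#' the 12 consecutive three-month windows, wrapping December into
#' January; the warmest (coldest) quarter of a cell is the window with
#' the highest (lowest) mean monthly mean temperature, ties broken by the
#' earliest starting month. Quarter selection is per cell.
#'
#' @param stack a [climate_stack()].
#' @return An object of class `bioclim_set`: six aligned layers named
#'   `annual_mean_temp`, `min_temp_coldest_month`,
#'   `max_temp_warmest_month` (degrees C), `annual_precip`,
#'   `precip_warmest_quarter`, `precip_coldest_quarter` (mm).
#' @examples
#' land <- generate_landscape(landscape_params(n_rows = 20, n_cols = 20))
#' bio <- derive_bioclim(land$climate)
#' names(bio$layers)
#' @export
derive_bioclim <- function(stack) {
  stopifnot(inherits(stack, "climate_stack"))
  for (var in c("tmin", "tmax", "prec"))
    for (m in 1:12)
      if (all(is.na(stack[[var]][, , m])))
        stop("fully masked layer: ", var, " month ", m)
  tmean <- (stack$tmin + stack$tmax) / 2
  nr <- stack$geometry$n_rows; nc <- stack$geometry$n_cols

  # quarter (3-month wrap-around window) means / totals, windows w = 1..12
  qtemp <- array(0, c(nr, nc, 12))
  qprec <- array(0, c(nr, nc, 12))
  for (w in 1:12) {
    months <- ((w - 1):(w + 1)) %% 12 + 1
    qtemp[, , w] <- (tmean[, , months[1]] + tmean[, , months[2]] +
                       tmean[, , months[3]]) / 3
    qprec[, , w] <- stack$prec[, , months[1]] + stack$prec[, , months[2]] +
      stack$prec[, , months[3]]
  }
  # which.max / which.min over the window axis; earliest window wins ties
  flat_q <- matrix(qtemp, nr * nc, 12)
  flat_p <- matrix(qprec, nr * nc, 12)
  ok <- !is.na(flat_q[, 1])
  warm <- cold <- rep(NA_integer_, nr * nc)
  warm[ok] <- max.col(flat_q[ok, , drop = FALSE], ties.method = "first")
  cold[ok] <- max.col(-flat_q[ok, , drop = FALSE], ties.method = "first")
  p_warm <- p_cold <- rep(NA_real_, nr * nc)
  p_warm[ok] <- flat_p[cbind(which(ok), warm[ok])]
  p_cold[ok] <- flat_p[cbind(which(ok), cold[ok])]

  layers <- list(
    annual_mean_temp = apply(tmean, c(1, 2), mean),
    min_temp_coldest_month = apply(stack$tmin, c(1, 2), min),
    max_temp_warmest_month = apply(stack$tmax, c(1, 2), max),
    annual_precip = apply(stack$prec, c(1, 2), sum),
    precip_warmest_quarter = matrix(p_warm, nr, nc),
    precip_coldest_quarter = matrix(p_cold, nr, nc)
  )
  structure(list(geometry = stack$geometry, layers = layers),
            class = "bioclim_set")
}

#' @export
print.bioclim_set <- function(x, ...) {
  cat(sprintf("<bioclim_set> %d x %d cells, %d nodata\n",
              x$geometry$n_rows, x$geometry$n_cols,
              sum(is.na(x$layers[[1]]))))
  for (nm in names(x$layers)) {
    v <- x$layers[[nm]]
    cat(sprintf("  %-24s %8.2f .. %8.2f\n", nm,
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' @rdname derive_bioclim
#' @param bioclim a `bioclim_set`.
#' @param name layer name.
#' @export
bioclim_layer <- function(bioclim, name) {
  if (!name %in% names(bioclim$layers))
    stop("no such bioclim layer: ", name)
  grid_layer(bioclim$geometry, bioclim$layers[[name]])
}

#' @rdname derive_bioclim
#' @export
bioclim_names <- function() {
  c("annual_mean_temp", "min_temp_coldest_month", "max_temp_warmest_month",
    "annual_precip", "precip_warmest_quarter", "precip_coldest_quarter")
}

# n_unmasked x 6 matrix of predictor values (rows = unmasked cells in
# column-major cell order), plus the index of those cells
bioclim_matrix <- function(bioclim) {
  mat <- sapply(bioclim$layers, as.vector)
  ok <- stats::complete.cases(mat)
  list(x = mat[ok, , drop = FALSE], cells = which(ok))
}

#' Write a bioclim set as six rasters
#'
#' @param bioclim a `bioclim_set`.
#' @param dir output directory; files are named after the layers.
#' @param format raster format.
#' @export
write_bioclim <- function(bioclim, dir, format = "esri_ascii") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "geotiff") "tif" else "asc"
  for (nm in names(bioclim$layers))
    write_raster(bioclim_layer(bioclim, nm),
                 file.path(dir, paste0(nm, ".", ext)), format)
  invisible(dir)
}

#' Apply GCM anomaly grids to a baseline climate stack
#'
#' Produces the future climate of one GCM x scenario by the delta
#' (anomaly) method: temperatures gain the additive anomaly; additive
#' precipitation anomalies are added and clamped at zero; relative
#' anomalies multiply the baseline. If the delta grids are coarser than
#' the baseline they are first resampled with [bicubic_upsample()].
#' Where the perturbed `tmin` would exceed `tmax` it is clamped to
#' `tmax` (a warning reports the cell count).
#'
#' @param current a [climate_stack()].
#' @param deltas a [delta_stack()].
#' @param precip_mode override of the delta stack's precipitation mode.
#' @return A `climate_stack` labelled `"{gcm}_{scenario}"`.
#' @export
apply_deltas <- function(current, deltas, precip_mode = NULL) {
  stopifnot(inherits(current, "climate_stack"), inherits(deltas, "delta_stack"))
  precip_mode <- if (is.null(precip_mode)) deltas$precip_mode else
    match.arg(precip_mode, c("relative", "additive"))
  geom <- current$geometry
  get_delta <- function(var, m) {
    if (geometry_aligned(geom, deltas$geometry)) return(deltas[[var]][, , m])
    up <- try(bicubic_upsample(grid_layer(deltas$geometry, deltas[[var]][, , m]),
                               geom), silent = TRUE)
    if (inherits(up, "try-error"))
      stop("delta grids are not aligned with the climate stack and cannot be resampled")
    up$values
  }
  dims <- c(geom$n_rows, geom$n_cols, 12)
  tmin <- array(NA_real_, dims); tmax <- array(NA_real_, dims)
  prec <- array(NA_real_, dims)
  for (m in 1:12) {
    tmin[, , m] <- current$tmin[, , m] + get_delta("tmin", m)
    tmax[, , m] <- current$tmax[, , m] + get_delta("tmax", m)
    dp <- get_delta("prec", m)
    prec[, , m] <- if (precip_mode == "additive")
      pmax(0, current$prec[, , m] + dp) else current$prec[, , m] * dp
  }
  n_clamp <- sum(tmin > tmax, na.rm = TRUE)
  if (n_clamp > 0) {
    warning(sprintf("clamped tmin to tmax at %d cell-months", n_clamp))
    tmin <- pmin(tmin, tmax)
  }
  prec <- pmax(prec, 0)
  climate_stack(geom, tmin, tmax, prec,
                period_label = paste(deltas$gcm_id, deltas$scenario_id, sep = "_"))
}
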