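#' Perturbation settings for the Monte Carlo uncertainty sources
#'
#' Collects the tunables of the uncertainty simulators. Defaults encode
#' the study conditions the framework was designed around: a 10-km mean
#' location error typical of coarse atlas records, 10% record loss
#' (biased or random), 100-fold cross-validation for model variance,
#' coarse noise-grid spacings of 0.5 degrees for monthly temperature and
#' 0.25 degrees for monthly precipitation (the scales at which spatial
#' correlation between interpolation errors becomes negligible; the
#' metric equivalents are used on projected grids), a 99% training share
#' for the combined-source bootstrap split, and 100 replicates.
#'
#' @param locational_mean_km mean Euclidean displacement of the location
#'   error, km.
#' @param locational_calibration how `locational_mean_km` parameterizes
#'   the isotropic Gaussian offset: `"mean_displacement"` (default;
#'   per-axis sd `mean_km / sqrt(pi/2)` so the Rayleigh mean equals
#'   `mean_km`), `"sigma"` (per-axis sd = `mean_km`), or
#'   `"mean_abs_axis"` (per-axis mean absolute offset = `mean_km`).
#' @param subsample_fraction fraction of records removed by the biased /
#'   random loss sources, in (0, 1).
#' @param cv_segments number of cross-validation segments for the
#'   model-variance source.
#' @param coarse_spacing_temp,coarse_spacing_prec spacing of the coarse
#'   climate-error noise grids, in map units; `NULL` picks the default
#'   for the grid's CRS (0.5 / 0.25 degrees, or their metric
#'   equivalents).
#' @param combined_train_fraction training share of the per-replicate
#'   bootstrap split used when all sources are combined.
#' @param combined_bias_mode whether the combined source removes records
#'   with the spatially biased (`"spatial_bias"`) or the random
#'   (`"random_loss"`) mechanism.
#' @param n_replicates Monte Carlo replicates per source.
#' @param master_seed master seed from which all replicate/source/
#'   variable sub-streams are derived (see [derive_seed()]).
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(locational_mean_km = 10,
                                locational_calibration = c("mean_displacement",
                                                           "sigma",
                                                           "mean_abs_axis"),
                                subsample_fraction = 0.10,
                                cv_segments = 100,
                                coarse_spacing_temp = NULL,
                                coarse_spacing_prec = NULL,
                                combined_train_fraction = 0.99,
                                combined_bias_mode = c("spatial_bias",
                                                       "random_loss"),
                                n_replicates = 100,
                                master_seed = 1) {
  locational_calibration <- match.arg(locational_calibration)
  combined_bias_mode <- match.arg(combined_bias_mode)
  stopifnot(locational_mean_km >= 0,
            subsample_fraction > 0, subsample_fraction < 1,
            combined_train_fraction > 0, combined_train_fraction < 1,
            cv_segments >= 1, n_replicates >= 1)
  structure(list(locational_mean_km = locational_mean_km,
                 locational_calibration = locational_calibration,
                 subsample_fraction = subsample_fraction,
                 cv_segments = as.integer(cv_segments),
                 coarse_spacing_temp = coarse_spacing_temp,
                 coarse_spacing_prec = coarse_spacing_prec,
                 combined_train_fraction = combined_train_fraction,
                 combined_bias_mode = combined_bias_mode,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "perturbation_config")
}

default_spacing <- function(cfg, var_kind, crs_kind) {
  sp <- if (var_kind == "prec") cfg$coarse_spacing_prec else cfg$coarse_spacing_temp
  if (!is.null(sp)) return(sp)
  deg <- if (var_kind == "prec") 0.25 else 0.5
  if (crs_kind == "geographic_degrees") deg else deg * KM_PER_DEGREE * 1000
}

#' Simulate locational uncertainty in occurrence records
#'
#' Displaces every record by an independent isotropic bivariate Gaussian
#' offset. Under the default calibration the per-axis standard deviation
#' is `mean_km / sqrt(pi / 2)`, so the mean Euclidean displacement (the
#' Rayleigh mean) equals `mean_km` — "an average of `mean_km` kilometres
#' of normally distributed noise". Kilometres are converted to map units
#' at each point's latitude on geographic grids (east-west offsets are
#' scaled by `cos(latitude)`).
#'
#' A point displaced outside the study region, or onto a masked cell
#' when `region` is supplied, is redrawn up to 100 times and then
#' dropped with a warning.
#'
#' @param occ an [occurrence_set()].
#' @param mean_km mean displacement in km; 0 returns the input unchanged.
#' @param rng_seed integer seed.
#' @param region optional `grid_layer` mask for validity checks.
#' @param calibration see [perturbation_config()].
#' @return A perturbed `occurrence_set`.
#' @export
perturb_locations <- function(occ, mean_km = 10, rng_seed = 1, region = NULL,
                              calibration = c("mean_displacement", "sigma",
                                              "mean_abs_axis")) {
  stopifnot(inherits(occ, "occurrence_set"), mean_km >= 0)
  calibration <- match.arg(calibration)
  if (mean_km == 0 || n_occurrences(occ) == 0) return(occ)
  sigma_km <- switch(calibration,
                     mean_displacement = mean_km / sqrt(pi / 2),
                     sigma = mean_km,
                     mean_abs_axis = mean_km * sqrt(pi / 2))
  geom <- occ$geometry
  rec <- occ$records
  with_seed(rng_seed, {
    n <- nrow(rec)
    new_x <- rec$x; new_y <- rec$y
    pending <- seq_len(n)
    for (attempt in 1:100) {
      if (length(pending) == 0) break
      m <- length(pending)
      dx_km <- stats::rnorm(m, 0, sigma_km)
      dy_km <- stats::rnorm(m, 0, sigma_km)
      if (geom$crs_kind == "geographic_degrees") {
        lat <- rec$y[pending]
        dy <- dy_km / KM_PER_DEGREE
        dx <- dx_km / (KM_PER_DEGREE * cos(lat * pi / 180))
      } else {
        dx <- dx_km * 1000; dy <- dy_km * 1000
      }
      cx <- rec$x[pending] + dx
      cy <- rec$y[pending] + dy
      idx <- point_to_cell(geom, cx, cy)
      ok <- !is.na(idx$row)
      if (!is.null(region))
        ok[ok] <- !is.na(region$values[cbind(idx$row[ok], idx$col[ok])])
      new_x[pending[ok]] <- cx[ok]
      new_y[pending[ok]] <- cy[ok]
      pending <- pending[!ok]
    }
    if (length(pending) > 0) {
      warning(length(pending), " record(s) could not be displaced onto the ",
              "study region after 100 attempts and were dropped")
      keep <- setdiff(seq_len(n), pending)
      rec <- rec[keep, , drop = FALSE]
      new_x <- new_x[keep]; new_y <- new_y[keep]
    }
    rec$x <- new_x; rec$y <- new_y
    structure(list(records = rec, geometry = geom), class = "occurrence_set")
  })
}

#' Simulate spatially biased record loss
#'
#' Draws an anchor point uniformly over the unmasked study region and
#' removes the `ceiling(fraction * n)` records farthest from it
#' (Euclidean distance on projected grids, great-circle on geographic
#' ones). Ties at the cutoff are broken by record-id order, so the
#' operation is deterministic given the seed. Removing a spatially
#' autocorrelated block of records in this way emulates geographically
#' concentrated gaps in sampling effort.
#'
#' @param occ an [occurrence_set()] with at least 2 records.
#' @param fraction fraction of records to remove, in (0, 1).
#' @param region `grid_layer` defining the region the anchor is drawn
#'   from (falls back to the full extent when `NULL`).
#' @param rng_seed integer seed.
#' @return The retained `occurrence_set`.
#' @export
biased_subsample <- function(occ, fraction = 0.10, region = NULL, rng_seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"))
  n <- n_occurrences(occ)
  if (n < 2) stop("biased_subsample needs at least 2 records")
  m <- n_removed(fraction, n)
  geom <- occ$geometry
  with_seed(rng_seed, {
    anchor <- random_region_point(geom, region)
    d <- if (geom$crs_kind == "geographic_degrees") {
      geosphere::distHaversine(cbind(occ$records$x, occ$records$y),
                               c(anchor$x, anchor$y))
    } else {
      sqrt((occ$records$x - anchor$x)^2 + (occ$records$y - anchor$y)^2)
    }
    ord <- order(-d, occ$records$id)
    keep_ids <- occ$records$id[-ord[seq_len(m)]]
    occ_subset(occ, occ$records$id[occ$records$id %in% keep_ids])
  })
}

#' Simulate random record loss
#'
#' Removes `ceiling(fraction * n)` records chosen uniformly without
#' replacement — the unbiased counterpart of [biased_subsample()], for
#' separating the effect of losing records from the effect of losing
#' them in a spatially structured way.
#'
#' @inheritParams biased_subsample
#' @return The retained `occurrence_set`.
#' @export
random_subsample <- function(occ, fraction = 0.10, rng_seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"))
  n <- n_occurrences(occ)
  m <- n_removed(fraction, n)
  with_seed(rng_seed, {
    drop <- sample.int(n, m)
    occ_subset(occ, occ$records$id[-drop])
  })
}

n_removed <- function(fraction, n) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- ceiling(fraction * n)
  m <- max(m, 1L)
  if (m >= n) stop("subsample fraction would remove every record")
  as.integer(m)
}

random_region_point <- function(geom, region) {
  if (!is.null(region)) {
    cells <- which(!is.na(region$values))
    pick <- cells[sample.int(length(cells), 1)]
    row <- (pick - 1) %% geom$n_rows + 1
    col <- (pick - 1) %/% geom$n_rows + 1
    cc <- cell_centers(geom)
    list(x = cc$x[col], y = cc$y[row])
  } else {
    list(x = geom$x_origin + stats::runif(1) * geom$n_cols * geom$cell_size,
         y = geom$y_origin - stats::runif(1) * geom$n_rows * geom$cell_size)
  }
}

#' Simulate spatially correlated climate measurement error
#'
#' Perturbs each of the 36 monthly climate layers with a spatially smooth
#' random error field, independently per variable: (1) a coarse grid at
#' the variable's spacing is laid over the study extent; (2) an
#' independent standard-normal deviate is drawn at each coarse node;
#' (3) the noise field is interpolated to the fine grid with
#' [bicubic_upsample()]; (4) it is scaled cell-wise by the
#' standard-error surface; (5) the result is added to the layer.
#' Precipitation is clamped at zero and `tmin` is clamped to `tmax`
#' (with a warning count). No cross-variable correlation is simulated:
#' correlations between 30-year monthly mean surfaces are negligible in
#' the context of their interpolation errors.
#'
#' Zero-valued error surfaces reproduce the input exactly. At cells
#' coinciding with coarse nodes the standard deviation of the perturbation
#' equals the error-surface value.
#'
#' @param stack a [climate_stack()].
#' @param errors an [error_surface_set()] aligned with `stack`.
#' @param cfg a [perturbation_config()] providing the coarse spacings.
#' @param rng_seed integer seed; each variable uses an independent
#'   sub-stream derived from it.
#' @return A perturbed `climate_stack`.
#' @export
simulate_climate_error <- function(stack, errors, cfg = perturbation_config(),
                                   rng_seed = 1) {
  stopifnot(inherits(stack, "climate_stack"),
            inherits(errors, "error_surface_set"))
  if (!geometry_aligned(stack$geometry, errors$geometry))
    stop("error surfaces are not aligned with the climate stack")
  geom <- stack$geometry
  out <- list(tmin = stack$tmin, tmax = stack$tmax, prec = stack$prec)
  var_index <- 0L
  for (var in c("tmin", "tmax", "prec")) {
    spacing <- default_spacing(cfg, if (var == "prec") "prec" else "temp",
                               geom$crs_kind)
    if (spacing < geom$cell_size)
      stop("coarse noise spacing (", spacing,
           ") must be at least the fine cell size (", geom$cell_size, ")")
    cgeom <- coarse_cover_geometry(geom, spacing)
    for (m in 1:12) {
      var_index <- var_index + 1L
      se <- errors[[var]][, , m]
      # a zero-SD layer is untouched; its sub-stream (keyed on the layer
      # index) is simply unused, so other layers' noise is unaffected
      if (all(se == 0, na.rm = TRUE)) next
      z <- with_seed(derive_seed(rng_seed, var_index), {
        matrix(stats::rnorm(cgeom$n_rows * cgeom$n_cols),
               cgeom$n_rows, cgeom$n_cols)
      })
      noise <- bicubic_upsample(grid_layer(cgeom, z), geom)
      out[[var]][, , m] <- out[[var]][, , m] + noise$values * se
    }
  }
  out$prec <- pmax(out$prec, 0)
  n_clamp <- sum(out$tmin > out$tmax, na.rm = TRUE)
  if (n_clamp > 0) {
    warning(sprintf("clamped tmin to tmax at %d cell-months", n_clamp))
    out$tmin <- pmin(out$tmin, out$tmax)
  }
  climate_stack(geom, out$tmin, out$tmax, out$prec,
                period_label = paste0(stack$period_label, "+error"))
}

# smallest coarse grid at `spacing` whose node hull covers the fine extent
# with one node of margin on every side
coarse_cover_geometry <- function(geom, spacing) {
  width <- geom$n_cols * geom$cell_size
  height <- geom$n_rows * geom$cell_size
  n_cols <- ceiling(width / spacing) + 2L
  n_rows <- ceiling(height / spacing) + 2L
  grid_geometry(n_rows, n_cols,
                x_origin = geom$x_origin - spacing,
                y_origin = geom$y_origin + spacing,
                cell_size = spacing, crs_kind = geom$crs_kind)
}

#' Set of standard-error surfaces for the 36 monthly climate layers
#'
#' Standard deviations (degrees C for temperature months, mm for
#' precipitation months) of the combined measurement and interpolation
#' error of each monthly climate surface, aligned with the climate stack
#' they describe. All unmasked values must be nonnegative.
#'
#' @inheritParams climate_stack
#' @return An object of class `error_surface_set`.
#' @export
error_surface_set <- function(geometry, tmin, tmax, prec) {
  dims <- c(geometry$n_rows, geometry$n_cols, 12L)
  for (nm in c("tmin", "tmax", "prec")) {
    a <- get(nm)
    if (!is.array(a) || !identical(as.integer(dim(a)), dims))
      stop(nm, " must be an n_rows x n_cols x 12 array")
    if (any(a < 0, na.rm = TRUE))
      stop("standard-error surfaces must be nonnegative (", nm, ")")
  }
  structure(list(geometry = geometry, tmin = tmin, tmax = tmax, prec = prec),
            class = "error_surface_set")
}

#' @export
print.error_surface_set <- function(x, ...) {
  cat(sprintf("<error_surface_set> %d x %d cells; mean SD tmin %.2f C, tmax %.2f C, prec %.1f mm\n",
              x$geometry$n_rows, x$geometry$n_cols,
              mean(x$tmin, na.rm = TRUE), mean(x$tmax, na.rm = TRUE),
              mean(x$prec, na.rm = TRUE)))
  invisible(x)
}

#' Read or write an error-surface set (36 rasters, `se_` prefix)
#'
#' @inheritParams read_climate_stack
#' @export
read_error_surfaces <- function(dir, format = "esri_ascii",
                                crs_kind = "projected_metric") {
  st <- read_climate_stack(dir, format, crs_kind, prefix = "se_",
                           period_label = "se")
  error_surface_set(st$geometry, st$tmin, st$tmax, st$prec)
}

#' @rdname read_error_surfaces
#' @param errors an `error_surface_set`.
#' @export
write_error_surfaces <- function(errors, dir, format = "esri_ascii") {
  st <- structure(list(geometry = errors$geometry, tmin = errors$tmin,
                       tmax = errors$tmax, prec = errors$prec),
                  class = "climate_stack")
  write_climate_stack(st, dir, format, prefix = "se_")
}

#' Partition records into cross-validation segments
#'
#' Randomly partitions the record ids into `k` disjoint, exhaustive
#' segments whose sizes differ by at most one. Replicate `r` of the
#' model-variance source trains on every record except segment `r`.
#'
#' @param occ an [occurrence_set()].
#' @param k number of segments, `k <= n`.
#' @param rng_seed integer seed.
#' @return A list of `k` character vectors of record ids.
#' @export
cv_segments <- function(occ, k = 100, rng_seed = 1) {
  n <- n_occurrences(occ)
  if (k > n) stop("cannot split ", n, " records into ", k, " segments")
  with_seed(rng_seed, {
    ids <- sample(occ$records$id)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(ids, rep(seq_len(k), times = sizes))
  })
}

#' Random training-testing split
#'
#' Splits the records into disjoint training and testing sets. Each call
#' is an independent draw, so testing sets from different replicates are
#' not mutually exclusive — a bootstrap-style alternative to
#' cross-validation used when all uncertainty sources are combined and
#' every replicate already carries different data.
#'
#' @param occ an [occurrence_set()].
#' @param train_fraction training share in (0, 1); the training size is
#'   `round half up` of `train_fraction * n`.
#' @param rng_seed integer seed.
#' @return A list with `occurrence_set`s `train` and `test`.
#' @export
bootstrap_split <- function(occ, train_fraction = 0.99, rng_seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_occurrences(occ)
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train < 5) stop("training split would leave fewer than 5 presences")
  if (n_train >= n) n_train <- n - 1L
  with_seed(rng_seed, {
    tr <- sample.int(n, n_train)
    list(train = occ_subset(occ, occ$records$id[sort(tr)]),
         test = occ_subset(occ, occ$records$id[-sort(tr)]))
  })
}
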