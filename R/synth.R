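#' Parameters of the synthetic landscape generator
#'
#' The generator emulates the statistical structure of interpolated
#' monthly climate surfaces over a coastal study region: smooth
#' latitudinal and elevation-driven temperature gradients with sinusoidal
#' seasonality, log-normal spatially correlated precipitation, a
#' clustered "coastline" mask, and standard-error surfaces that are
#' larger where the temperature field's local gradient is steeper (as
#' interpolation error is in rough terrain).
#'
#' @param n_rows,n_cols grid size (default 100 x 100).
#' @param cell_size cell size in map units (default 1000 m).
#' @param crs_kind CRS kind of the landscape.
#' @param base_temp annual mean temperature at the northern edge at sea
#'   level, degrees C.
#' @param lat_gradient temperature change per map unit of northing
#'   (default -5 C per 100 km, i.e. cooler to the south).
#' @param seasonal_amplitude half-range of the monthly mean temperature
#'   cycle, degrees C.
#' @param warmest_month month (1-12) at the peak of the seasonal cycle.
#' @param diurnal_range `tmax - tmin`, degrees C (>= 2).
#' @param elevation_relief maximum height of the smooth synthetic
#'   elevation field, map-vertical units (m); temperatures fall with a
#'   0.0065 C/m lapse rate.
#' @param mean_precip annual-mean monthly precipitation, mm.
#' @param precip_sdlog log-scale dispersion of the log-normal
#'   precipitation field.
#' @param correlation_length distance (map units) at which the spatial
#'   autocorrelation of the precipitation noise falls to `exp(-1)`.
#' @param mask_fraction fraction of cells masked out as "sea" (0 for no
#'   mask).
#' @param rng_seed integer seed.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(n_rows = 100, n_cols = 100, cell_size = 1000,
                             crs_kind = "projected_metric",
                             base_temp = 12, lat_gradient = -5e-5,
                             seasonal_amplitude = 6, warmest_month = 2,
                             diurnal_range = 8, elevation_relief = 800,
                             mean_precip = 80, precip_sdlog = 0.4,
                             correlation_length = 10000,
                             mask_fraction = 0.15, rng_seed = 1) {
  stopifnot(diurnal_range >= 2, correlation_length >= cell_size,
            mask_fraction >= 0, mask_fraction < 1, mean_precip > 0)
  structure(as.list(environment()), class = "landscape_params")
}

#' Generate a synthetic landscape with known structure
#'
#' Builds a 12-month climate stack and matching standard-error surfaces
#' from [landscape_params()]. All outputs satisfy the climate-stack
#' invariants by construction (`tmax - tmin >= 2` C, `prec >= 0`,
#' aligned layers, harmonised mask); the same seed reproduces the same
#' landscape bit for bit.
#'
#' @param params a [landscape_params()].
#' @return A list with elements `climate` ([climate_stack()]), `errors`
#'   ([error_surface_set()]), `elevation` (`grid_layer`), and `params`.
#' @export
generate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  p <- params
  geom <- grid_geometry(p$n_rows, p$n_cols, 0, p$n_rows * p$cell_size,
                        p$cell_size, p$crs_kind)
  nr <- p$n_rows; nc <- p$n_cols
  cc <- cell_centers(geom)

  with_seed(p$rng_seed, {
    # smooth pseudo-elevation: correlated Gaussian field, shifted positive
    elev_raw <- gaussian_random_field(nr, nc, p$correlation_length / p$cell_size)
    elev <- (elev_raw - min(elev_raw)) / diff(range(elev_raw)) * p$elevation_relief

    # clustered sea mask: lowest-"elevation" cells, threshold by quantile
    mask <- matrix(FALSE, nr, nc)
    if (p$mask_fraction > 0)
      mask <- elev <= stats::quantile(elev, p$mask_fraction)

    northing <- matrix(rep(cc$y, nc), nr, nc)
    annual_tmean <- p$base_temp +
      p$lat_gradient * (northing - geom$y_origin) - 0.0065 * elev

    dims <- c(nr, nc, 12)
    tmin <- array(NA_real_, dims); tmax <- array(NA_real_, dims)
    prec <- array(NA_real_, dims)
    # seasonal amplitude strengthens with elevation (continentality);
    # diurnal range follows an independent smooth "cloudiness" field and
    # widens in the warm season, so the three temperature predictors are
    # correlated but not collinear
    relief <- elev / max(elev)
    cloud <- gaussian_random_field(nr, nc, p$correlation_length / p$cell_size)
    cloud <- (cloud - min(cloud)) / diff(range(cloud))
    amp <- p$seasonal_amplitude * (0.85 + 0.3 * relief)
    dr <- pmax(p$diurnal_range * (0.8 + 0.4 * cloud), 2)
    season <- cos(2 * pi * ((1:12) - p$warmest_month) / 12)
    wet_season <- 1 + 0.4 * cos(2 * pi * ((1:12) - p$warmest_month - 6) / 12)
    for (m in 1:12) {
      tmean_m <- annual_tmean + amp * season[m]
      dr_m <- pmax(dr * (1 + 0.25 * season[m]), 2)
      tmin[, , m] <- tmean_m - dr_m / 2
      tmax[, , m] <- tmean_m + dr_m / 2
      z <- gaussian_random_field(nr, nc, p$correlation_length / p$cell_size)
      prec[, , m] <- p$mean_precip * wet_season[m] * exp(p$precip_sdlog * z)
    }
    for (m in 1:12) {
      tmin[, , m][mask] <- NA_real_
      tmax[, , m][mask] <- NA_real_
      prec[, , m][mask] <- NA_real_
    }
    climate <- climate_stack(geom, tmin, tmax, prec, period_label = "current")

    # error surfaces scale with the local slope of the temperature field
    grad <- gradient_magnitude(annual_tmean, p$cell_size)
    rough <- grad / max(grad[!mask])
    se_t <- 0.15 + 0.6 * rough              # degrees C
    se_p <- 4 + 16 * rough                  # mm
    eset <- list(tmin = array(NA_real_, dims), tmax = array(NA_real_, dims),
                 prec = array(NA_real_, dims))
    for (m in 1:12) {
      eset$tmin[, , m] <- ifelse(mask, NA_real_, se_t)
      eset$tmax[, , m] <- ifelse(mask, NA_real_, se_t)
      eset$prec[, , m] <- ifelse(mask, NA_real_, se_p)
    }
    errors <- error_surface_set(geom, eset$tmin, eset$tmax, eset$prec)
    elev[mask] <- NA_real_
    list(climate = climate, errors = errors,
         elevation = grid_layer(geom, elev), params = params)
  })
}

#' @rdname generate_landscape
#' @param landscape result of `generate_landscape()`.
#' @export
landscape_region <- function(landscape) region_layer(landscape$climate)

# stationary unit-variance Gaussian random field whose autocorrelation at
# distance d (in cells) is exp(-d^2 / L^2): white noise convolved with a
# Gaussian kernel of sd L/2 via circular (FFT) convolution. Scaling by the
# exact filter norm (rather than per-field empirical moments) keeps the
# field stationary and its correlation structure undistorted.
gaussian_random_field <- function(nr, nc, length_cells) {
  s <- max(length_cells / 2, 1e-6)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  kr <- gauss_kernel_1d(nr, s)
  kc <- gauss_kernel_1d(nc, s)
  kernel <- outer(kr, kc)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kernel), inverse = TRUE)) /
    (nr * nc)
  sm / sqrt(sum(kernel^2))
}

gauss_kernel_1d <- function(n, s) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-d^2 / (2 * s^2))
  k / sum(k)
}

gradient_magnitude <- function(m, cell_size) {
  gx <- m; gy <- m
  gx[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]; gx[, ncol(m)] <- m[, ncol(m)] - m[, ncol(m) - 1]
  gy[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]; gy[nrow(m), ] <- m[nrow(m), ] - m[nrow(m) - 1, ]
  sqrt(gx^2 + gy^2) / cell_size
}

#' A known ("virtual species") niche on the bioclim predictors
#'
#' True logistic suitability `plogis(intercept + sum(beta * z))` where
#' `z` are the named bioclim layers standardized over the landscape's
#' unmasked cells. Used to sample occurrences with known ground truth so
#' that model recovery can be checked against the generating
#' coefficients.
#'
#' @param coefficients named numeric vector of true coefficients on
#'   bioclim variables (names from [bioclim_names()]).
#' @param intercept true intercept on the logit scale.
#' @param prevalence optional target mean suitability in (0, 1); when
#'   given, the intercept is solved so the mean true suitability over
#'   unmasked cells equals it.
#' @param predictors the `bioclim_set` the niche lives on (supplies the
#'   standardization).
#' @return An object of class `synthetic_niche` with a `$suitability`
#'   `grid_layer` (the truth raster).
#' @export
synthetic_niche <- function(coefficients, intercept = 0, prevalence = NULL,
                            predictors) {
  stopifnot(inherits(predictors, "bioclim_set"),
            all(names(coefficients) %in% bioclim_names()))
  bm <- bioclim_matrix(predictors)
  z <- scale(bm$x[, names(coefficients), drop = FALSE])
  eta <- as.numeric(z %*% coefficients)
  if (!is.null(prevalence)) {
    stopifnot(prevalence > 0, prevalence < 1)
    intercept <- stats::uniroot(function(b) mean(plogis(b + eta)) - prevalence,
                                c(-50, 50), tol = 1e-10)$root
  }
  s <- rep(NA_real_, predictors$geometry$n_rows * predictors$geometry$n_cols)
  s[bm$cells] <- plogis(intercept + eta)
  structure(list(coefficients = coefficients, intercept = intercept,
                 suitability = grid_layer(predictors$geometry,
                                          matrix(s, predictors$geometry$n_rows,
                                                 predictors$geometry$n_cols))),
            class = "synthetic_niche")
}

#' @rdname synthetic_niche
#' @export
default_niche <- function(predictors) {
  synthetic_niche(c(annual_mean_temp = 2, annual_precip = 1.2),
                  prevalence = 0.15, predictors = predictors)
}

#' Sample virtual-species occurrences from a known niche
#'
#' Samples `n` cells without replacement with probability proportional
#' to true suitability, and places one record at each sampled cell
#' centre. Cells with zero suitability are never sampled.
#'
#' @param niche a [synthetic_niche()].
#' @param predictors the `bioclim_set` the niche was built on (geometry
#'   reference).
#' @param n number of records.
#' @param rng_seed integer seed.
#' @return An [occurrence_set()]; the truth raster remains available as
#'   `niche$suitability`.
#' @export
generate_occurrences <- function(niche, predictors, n, rng_seed = 1) {
  stopifnot(inherits(niche, "synthetic_niche"), n >= 0)
  s <- niche$suitability$values
  cells <- which(!is.na(s) & s > 0)
  if (length(cells) == 0) stop("the niche has no cell with positive suitability")
  geom <- niche$suitability$geometry
  if (n == 0)
    return(occurrence_set(data.frame(id = character(0), x = numeric(0),
                                     y = numeric(0)), geom))
  if (n > length(cells))
    stop("cannot sample ", n, " occurrences from ", length(cells),
         " suitable cells without replacement")
  picked <- with_seed(rng_seed, sample(cells, n, prob = s[cells]))
  row <- (picked - 1) %% geom$n_rows + 1
  col <- (picked - 1) %/% geom$n_rows + 1
  cc <- cell_centers(geom)
  occurrence_set(data.frame(id = sprintf("occ%05d", seq_len(n)),
                            x = cc$x[col], y = cc$y[row]), geom)
}

#' Generate GCM-like anomaly stacks
#'
#' Builds one [delta_stack()] per (GCM profile, emissions scenario)
#' combination. Each profile is a mean warming (degrees C) and a
#' precipitation ratio; each scenario is a scale factor (a low-emissions
#' scenario scales anomalies down, giving changes that are qualitatively
#' similar but smaller in magnitude). Anomalies vary smoothly in space
#' through a deterministic sinusoidal modulation, so a scale factor of 0
#' yields exact identity deltas (0 C, ratio 1) and halving the scale
#' exactly halves every anomaly.
#'
#' @param geometry target `grid_geometry`.
#' @param gcm_profiles data frame with columns `gcm_id`, `warming`
#'   (degrees C), `precip_ratio`; defaults to six contrasting profiles
#'   spanning wetter-and-cooler to warmer-and-drier.
#' @param scenarios data frame with columns `scenario_id`, `scale`;
#'   defaults to a high (A2, scale 1) and a low (B1, scale 0.55)
#'   emissions scenario.
#' @param target_year centre year of the future period.
#' @return A list of `delta_stack`s, one per profile x scenario.
#' @export
generate_deltas <- function(geometry,
                            gcm_profiles = default_gcm_profiles(),
                            scenarios = data.frame(scenario_id = c("A2", "B1"),
                                                   scale = c(1, 0.55)),
                            target_year = 2085) {
  stopifnot(nrow(gcm_profiles) >= 1, nrow(scenarios) >= 1)
  nr <- geometry$n_rows; nc <- geometry$n_cols
  cc <- cell_centers(geometry)
  # smooth unit-mean spatial modulation in [0.8, 1.2]
  fx <- outer(seq_len(nr), seq_len(nc), function(i, j)
    1 + 0.2 * sin(2 * pi * i / nr) * cos(2 * pi * j / nc))
  out <- list()
  for (g in seq_len(nrow(gcm_profiles))) {
    for (s in seq_len(nrow(scenarios))) {
      warm <- gcm_profiles$warming[g] * scenarios$scale[s] * fx
      pr <- 1 + (gcm_profiles$precip_ratio[g] - 1) * scenarios$scale[s] * fx
      dims <- c(nr, nc, 12)
      tmin <- array(rep(warm, 12), dims)
      tmax <- array(rep(warm, 12), dims)
      prec <- array(rep(pr, 12), dims)
      out[[length(out) + 1]] <- delta_stack(
        geometry, tmin, tmax, prec,
        gcm_id = gcm_profiles$gcm_id[g],
        scenario_id = scenarios$scenario_id[s],
        target_year = target_year, precip_mode = "relative")
    }
  }
  out
}

#' @rdname generate_deltas
#' @export
default_gcm_profiles <- function() {
  data.frame(
    gcm_id = c("wetcool", "warmdry", "hot", "mild", "wet", "dry"),
    warming = c(1.8, 3.4, 3.8, 2.0, 2.6, 3.0),
    precip_ratio = c(1.12, 0.85, 0.95, 1.02, 1.18, 0.80))
}

#' Write a complete synthetic fixture directory
#'
#' Generates a landscape, a virtual species, error surfaces and GCM-like
#' deltas, and writes them in the layout the pipeline consumes:
#' `climate/` (36 rasters), `errors/` (36 `se_` rasters),
#' `deltas/{gcm}_{scenario}/` (36 rasters each), `occurrences.csv`, and
#' `truth/suitability.asc`.
#'
#' @param dir output directory.
#' @param params a [landscape_params()].
#' @param n_occurrences number of virtual-species records.
#' @param niche_coefficients named true coefficients (see
#'   [synthetic_niche()]).
#' @param prevalence target mean true suitability.
#' @param gcm_profiles,scenarios passed to [generate_deltas()].
#' @param format raster format for all layers.
#' @param rng_seed seed for the occurrence draw (the landscape uses
#'   `params$rng_seed`).
#' @return Invisibly, the in-memory fixture (as from [synth_fixture()]).
#' @export
write_synth_fixture <- function(dir, params = landscape_params(),
                                n_occurrences = 300,
                                niche_coefficients = c(annual_mean_temp = 2,
                                                       annual_precip = 1.2),
                                prevalence = 0.15,
                                gcm_profiles = default_gcm_profiles(),
                                scenarios = data.frame(scenario_id = c("A2", "B1"),
                                                       scale = c(1, 0.55)),
                                format = "esri_ascii", rng_seed = 1) {
  fx <- synth_fixture(params = params, n_occurrences = n_occurrences,
                      niche_coefficients = niche_coefficients,
                      prevalence = prevalence, gcm_profiles = gcm_profiles,
                      scenarios = scenarios, rng_seed = rng_seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_climate_stack(fx$climate, file.path(dir, "climate"), format)
  write_error_surfaces(fx$errors, file.path(dir, "errors"), format)
  for (d in fx$deltas) {
    sub <- file.path(dir, "deltas", paste(d$gcm_id, d$scenario_id, sep = "_"))
    st <- structure(list(geometry = d$geometry, tmin = d$tmin, tmax = d$tmax,
                         prec = d$prec), class = "climate_stack")
    write_climate_stack(st, sub, format)
    writeLines(yaml::as.yaml(list(gcm_id = d$gcm_id,
                                  scenario_id = d$scenario_id,
                                  target_year = d$target_year,
                                  precip_mode = d$precip_mode)),
               file.path(sub, "delta.yaml"))
  }
  write_occurrences(fx$occurrences, file.path(dir, "occurrences.csv"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_raster(fx$niche$suitability,
               file.path(dir, "truth", if (format == "geotiff")
                 "suitability.tif" else "suitability.asc"), format)
  invisible(fx)
}

#' @rdname write_synth_fixture
#' @param ... passed on to [landscape_params()] when `params` is not
#'   given.
#' @export
synth_fixture <- function(params = NULL, n_occurrences = 300,
                          niche_coefficients = c(annual_mean_temp = 2,
                                                 annual_precip = 1.2),
                          prevalence = 0.15,
                          gcm_profiles = default_gcm_profiles(),
                          scenarios = data.frame(scenario_id = c("A2", "B1"),
                                                 scale = c(1, 0.55)),
                          rng_seed = 1, ...) {
  if (is.null(params)) params <- landscape_params(...)
  land <- generate_landscape(params)
  bio <- derive_bioclim(land$climate)
  niche <- synthetic_niche(niche_coefficients, prevalence = prevalence,
                           predictors = bio)
  occ <- generate_occurrences(niche, bio, n_occurrences,
                              rng_seed = derive_seed(rng_seed, 1))
  deltas <- generate_deltas(land$climate$geometry, gcm_profiles, scenarios)
  list(climate = land$climate, errors = land$errors, elevation = land$elevation,
       bioclim = bio, niche = niche, occurrences = occ, deltas = deltas,
       params = params)
}
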