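#' Uncertainty-source specification
#'
#' Identifies which perturbation mechanisms a Monte Carlo run simulates:
#' `baseline` (a single unperturbed fit), `locational` (occurrence
#' location error), `spatial_bias` / `random_loss` (structured vs random
#' record loss), `climate_error` (spatially correlated climate
#' measurement error), `model_variance` (cross-validation refits), or
#' `combined` (location error + record loss + climate error + a random
#' training-testing split per replicate, applied simultaneously).
#'
#' @param source_id one of the ids above.
#' @param cfg a [perturbation_config()].
#' @return An object of class `source_spec`; for `baseline` the
#'   replicate count is 1, for `model_variance` it equals
#'   `cfg$cv_segments`, otherwise `cfg$n_replicates`.
#' @export
source_spec <- function(source_id = c("baseline", "locational", "spatial_bias",
                                      "random_loss", "climate_error",
                                      "model_variance", "combined"),
                        cfg = perturbation_config()) {
  source_id <- match.arg(source_id)
  n_rep <- switch(source_id,
                  baseline = 1L,
                  model_variance = cfg$cv_segments,
                  cfg$n_replicates)
  structure(list(source_id = source_id, n_replicates = n_rep),
            class = "source_spec")
}

#' Per-cell presence probability across Monte Carlo replicates
#'
#' The central output of the framework: for each cell, the proportion of
#' successful model replicates whose thresholded prediction classifies
#' the cell as a presence. Values are multiples of
#' `1 / n_replicates`; masked cells are the union of the replicate
#' masks.
#'
#' @param binary_maps list of aligned binary `grid_layer`s (one per
#'   replicate).
#' @param source_id,scenario labels carried on the result.
#' @return An object of class `presence_probability_map` wrapping the
#'   probability `grid_layer` (`$grid`), with `print` and `plot`
#'   methods.
#' @export
aggregate_presence_probability <- function(binary_maps, source_id = "unknown",
                                           scenario = "current") {
  stopifnot(length(binary_maps) >= 1)
  geom <- binary_maps[[1]]$geometry
  acc <- matrix(0, geom$n_rows, geom$n_cols)
  mask <- matrix(FALSE, geom$n_rows, geom$n_cols)
  for (b in binary_maps) {
    stopifnot(inherits(b, "grid_layer"))
    if (!geometry_aligned(geom, b$geometry))
      stop("binary maps are not aligned")
    mask <- mask | is.na(b$values)
    v <- b$values
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  p <- acc / length(binary_maps)
  p[mask] <- NA_real_
  new_probability_map(grid_layer(geom, p), length(binary_maps), source_id,
                      scenario)
}

new_probability_map <- function(grid, n_replicates, source_id, scenario) {
  structure(list(grid = grid, n_replicates = n_replicates,
                 source_id = source_id, scenario = scenario),
            class = "presence_probability_map")
}

#' @export
print.presence_probability_map <- function(x, ...) {
  v <- x$grid$values
  cat(sprintf("<presence_probability_map> source '%s', scenario '%s', %d replicate(s)\n",
              x$source_id, x$scenario, x$n_replicates))
  cat(sprintf("  %d x %d cells; mean presence probability %.3f; %.1f%% of cells uncertain (0 < p < 1)\n",
              x$grid$geometry$n_rows, x$grid$geometry$n_cols,
              mean(v, na.rm = TRUE),
              100 * mean(v > 0 & v < 1, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.presence_probability_map <- function(x, ...,
                                          col = grDevices::hcl.colors(64, "viridis"),
                                          mask_col = "grey80") {
  geom <- x$grid$geometry
  cc <- cell_centers(geom)
  z <- t(x$grid$values[geom$n_rows:1, , drop = FALSE])
  graphics::image(cc$x, rev(cc$y), matrix(mask_col != "", length(cc$x),
                                          length(cc$y)),
                  col = mask_col, axes = TRUE, xlab = "x", ylab = "y",
                  main = sprintf("%s / %s: proportion of runs predicting presence",
                                 x$source_id, x$scenario))
  graphics::image(cc$x, rev(cc$y), z, col = col, zlim = c(0, 1), add = TRUE)
  invisible(x)
}

#' Run the Monte Carlo loop for one uncertainty source
#'
#' For each replicate the inputs are perturbed according to the source, a
#' suitability model is refit on the perturbed occurrences against the
#' (possibly perturbed) current climate, the per-replicate threshold is
#' computed on the training data, and the thresholded prediction is
#' recorded; the binary maps are aggregated into a per-cell presence
#' probability. Models are always fit on current-climate predictors and
#' projected onto the scenario's predictors within the same replicate.
#'
#' Replicates that fail (for example, too few presences after
#' perturbation) are logged and excluded from the denominator; more than
#' 20% failures aborts the run with a diagnostic.
#'
#' @param occ presence [occurrence_set()].
#' @param current_climate baseline [climate_stack()].
#' @param errors [error_surface_set()]; required by the `climate_error`
#'   and `combined` sources.
#' @param cfg a [perturbation_config()].
#' @param source a [source_spec()] or source id string.
#' @param deltas list of [delta_stack()]s defining the future scenarios
#'   (may be empty).
#' @param rule a [threshold_rule()].
#' @param background optional pre-sampled background [occurrence_set()];
#'   by default `background_n` points (capped at the number of unmasked
#'   cells) are sampled once per run from the master seed.
#' @param background_n background sample size.
#' @param reg_weight ridge penalty passed to [fit_sdm()].
#' @return `run_scenario_matrix()` returns a named list of
#'   [aggregate_presence_probability()] maps: `current` plus one per
#'   GCM x scenario delta. `run_source()` returns the single map for the
#'   requested scenario (default `current`).
#' @examples
#' \donttest{
#' fx <- synth_fixture(n_rows = 40, n_cols = 40, n_occurrences = 150)
#' cfg <- perturbation_config(n_replicates = 10, master_seed = 7)
#' maps <- run_scenario_matrix(fx$occurrences, fx$climate, fx$errors,
#'                             fx$deltas[1], cfg, "locational")
#' maps$current
#' }
#' @export
run_scenario_matrix <- function(occ, current_climate, errors = NULL,
                                deltas = list(), cfg = perturbation_config(),
                                source = "baseline",
                                rule = threshold_rule("max_sens_plus_spec"),
                                background = NULL, background_n = 10000,
                                reg_weight = 0.01) {
  if (!inherits(source, "source_spec")) source <- source_spec(source, cfg)
  stopifnot(inherits(occ, "occurrence_set"),
            inherits(current_climate, "climate_stack"))
  if (source$source_id %in% c("climate_error", "combined") && is.null(errors))
    stop("the '", source$source_id, "' source requires error surfaces")

  geom <- current_climate$geometry
  region <- region_layer(current_climate)
  labels <- c("current", vapply(deltas, function(d)
    paste(d$gcm_id, d$scenario_id, sep = "_"), character(1)))
  if (anyDuplicated(labels))
    stop("duplicate (gcm, scenario) labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))

  if (is.null(background)) {
    n_bg <- min(background_n, sum(!is.na(region$values)) - 1L)
    background <- sample_background(region, n_bg,
                                    rng_seed = derive_seed(cfg$master_seed, 100))
  }

  perturbs_climate <- source$source_id %in% c("climate_error", "combined")
  # predictors are invariant across replicates unless climate is perturbed
  base_bio <- derive_bioclim(current_climate)
  base_scen_bio <- if (!perturbs_climate)
    lapply(deltas, function(d) derive_bioclim(apply_deltas(current_climate, d)))
  else NULL

  segments <- if (source$source_id == "model_variance") {
    cv_segments(occ, cfg$cv_segments, derive_seed(cfg$master_seed, 106))
  } else NULL

  n_rep <- source$n_replicates
  acc <- lapply(labels, function(...) matrix(0, geom$n_rows, geom$n_cols))
  mask <- matrix(FALSE, geom$n_rows, geom$n_cols)
  names(acc) <- labels
  n_ok <- 0L
  failures <- character(0)
  areas <- stats::setNames(rep(list(numeric(0)), length(labels)), labels)

  for (r in seq_len(n_rep)) {
    res <- tryCatch(suppressWarnings(
      replicate_maps(occ, current_climate, errors, cfg, source, deltas, rule,
                     background, reg_weight, region, base_bio, base_scen_bio,
                     segments, r)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("replicate %d: %s", r, res))
      next
    }
    n_ok <- n_ok + 1L
    for (lab in labels) {
      v <- res[[lab]]$values
      areas[[lab]] <- c(areas[[lab]], mean(v, na.rm = TRUE))
      mask <- mask | is.na(v)
      v[is.na(v)] <- 0
      acc[[lab]] <- acc[[lab]] + v
    }
  }
  if (length(failures) > 0.2 * n_rep || n_ok == 0)
    stop("too many failed replicates (", length(failures), "/", n_rep, "): ",
         paste(utils::head(failures, 3), collapse = "; "))
  if (length(failures) > 0)
    warning(length(failures), " replicate(s) failed and were excluded: ",
            paste(utils::head(failures, 3), collapse = "; "))

  out <- lapply(labels, function(lab) {
    p <- acc[[lab]] / n_ok
    p[mask] <- NA_real_
    new_probability_map(grid_layer(geom, p), n_ok, source$source_id, lab)
  })
  names(out) <- labels
  attr(out, "failures") <- failures
  # per-replicate predicted-presence fractions, useful for comparing the
  # spread of sources beyond Monte Carlo error
  attr(out, "replicate_areas") <- areas
  out
}

#' @rdname run_scenario_matrix
#' @param scenario a single [delta_stack()] for a future scenario, or
#'   `NULL` for current climate.
#' @export
run_source <- function(occ, current_climate, errors = NULL,
                       cfg = perturbation_config(), source = "baseline",
                       scenario = NULL, ...) {
  deltas <- if (is.null(scenario)) list() else list(scenario)
  maps <- run_scenario_matrix(occ, current_climate, errors, deltas, cfg,
                              source, ...)
  maps[[length(maps)]]
}

# one replicate: perturb inputs, refit, threshold, predict per scenario
replicate_maps <- function(occ, current_climate, errors, cfg, source, deltas,
                           rule, background, reg_weight, region, base_bio,
                           base_scen_bio, segments, r) {
  ms <- cfg$master_seed
  sid <- source$source_id
  occ_r <- occ
  if (sid %in% c("locational", "combined"))
    occ_r <- perturb_locations(occ_r, cfg$locational_mean_km,
                               derive_seed(ms, 101, r), region,
                               cfg$locational_calibration)
  if (sid == "spatial_bias" ||
      (sid == "combined" && cfg$combined_bias_mode == "spatial_bias"))
    occ_r <- biased_subsample(occ_r, cfg$subsample_fraction, region,
                              derive_seed(ms, 102, r))
  if (sid == "random_loss" ||
      (sid == "combined" && cfg$combined_bias_mode == "random_loss"))
    occ_r <- random_subsample(occ_r, cfg$subsample_fraction,
                              derive_seed(ms, 103, r))
  if (sid == "model_variance")
    occ_r <- occ_subset(occ_r, setdiff(occ_r$records$id, segments[[r]]))
  if (sid == "combined")
    occ_r <- bootstrap_split(occ_r, cfg$combined_train_fraction,
                             derive_seed(ms, 105, r))$train

  if (sid %in% c("climate_error", "combined")) {
    clim_r <- simulate_climate_error(current_climate, errors, cfg,
                                     derive_seed(ms, 104, r))
    bio_fit <- derive_bioclim(clim_r)
    scen_bio <- lapply(deltas, function(d) derive_bioclim(apply_deltas(clim_r, d)))
  } else {
    bio_fit <- base_bio
    scen_bio <- base_scen_bio
  }

  fit <- fit_sdm(occ_r, background, bio_fit, reg_weight,
                 rng_seed = derive_seed(ms, 107, r))
  suit <- predict_suitability(fit, bio_fit)
  thr <- compute_threshold(fit, occ_r, background, suit, rule)
  out <- list(current = threshold_map(suit, thr))
  for (k in seq_along(deltas)) {
    lab <- paste(deltas[[k]]$gcm_id, deltas[[k]]$scenario_id, sep = "_")
    out[[lab]] <- threshold_map(predict_suitability(fit, scen_bio[[k]]), thr)
  }
  out
}

# study-region layer (1 = modelled, NA = outside) from a climate stack mask
region_layer <- function(stack) {
  v <- matrix(1, stack$geometry$n_rows, stack$geometry$n_cols)
  v[stack$mask] <- NA_real_
  grid_layer(stack$geometry, v)
}
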