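#' Load and validate a pipeline run configuration
#'
#' The YAML configuration drives a whole run: input paths, perturbation
#' settings, SDM backend settings, threshold rule, the uncertainty
#' sources to simulate, and the master seed. Validation is strict —
#' unknown keys are rejected with the offending key named — and happens
#' before any computation.
#'
#' @param path YAML file path, or a list already parsed.
#' @return A validated object of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  schema <- list(
    paths = c("climate_dir", "errors_dir", "deltas_dir", "occurrences",
              "output_dir"),
    perturbations = list(
      locational = c("mean_km", "calibration"),
      subsample = c("fraction"),
      model_variance = c("segments"),
      climate_error = c("coarse_spacing_temp", "coarse_spacing_prec"),
      combined = c("train_fraction", "bias_mode")),
    sdm = c("reg_weight", "background_n"),
    threshold = c("rule", "parameter"),
    top = c("paths", "perturbations", "sdm", "threshold", "sources",
            "n_replicates", "master_seed", "species", "raster_format",
            "crs_kind", "precip_mode", "log_level"))
  check_keys(cfg, schema$top, "top level")
  if (!is.null(cfg$paths)) check_keys(cfg$paths, schema$paths, "paths")
  if (!is.null(cfg$perturbations)) {
    check_keys(cfg$perturbations, names(schema$perturbations), "perturbations")
    for (blk in names(schema$perturbations))
      if (!is.null(cfg$perturbations[[blk]]))
        check_keys(cfg$perturbations[[blk]], schema$perturbations[[blk]],
                   paste0("perturbations$", blk))
  }
  if (!is.null(cfg$sdm)) check_keys(cfg$sdm, schema$sdm, "sdm")
  if (!is.null(cfg$threshold)) check_keys(cfg$threshold, schema$threshold,
                                          "threshold")
  gv <- function(x, default) if (is.null(x)) default else x
  pp <- gv(cfg$perturbations, list())
  pcfg <- perturbation_config(
    locational_mean_km = gv(pp$locational$mean_km, 10),
    locational_calibration = gv(pp$locational$calibration, "mean_displacement"),
    subsample_fraction = gv(pp$subsample$fraction, 0.10),
    cv_segments = gv(pp$model_variance$segments, 100),
    coarse_spacing_temp = pp$climate_error$coarse_spacing_temp,
    coarse_spacing_prec = pp$climate_error$coarse_spacing_prec,
    combined_train_fraction = gv(pp$combined$train_fraction, 0.99),
    combined_bias_mode = gv(pp$combined$bias_mode, "spatial_bias"),
    n_replicates = gv(cfg$n_replicates, 100),
    master_seed = gv(cfg$master_seed, 1))
  sources <- gv(cfg$sources, "baseline")
  valid <- c("baseline", "locational", "spatial_bias", "random_loss",
             "climate_error", "model_variance", "combined")
  bad <- setdiff(sources, valid)
  if (length(bad)) stop("unknown source id(s): ", paste(bad, collapse = ", "))
  rule <- threshold_rule(gv(cfg$threshold$rule, "max_sens_plus_spec"),
                         gv(cfg$threshold$parameter, NA_real_))
  structure(list(
    paths = cfg$paths,
    perturbations = pcfg,
    sources = sources,
    rule = rule,
    species = gv(cfg$species, "species"),
    raster_format = match.arg(gv(cfg$raster_format, "esri_ascii"),
                              c("esri_ascii", "geotiff")),
    crs_kind = match.arg(gv(cfg$crs_kind, "projected_metric"),
                         c("projected_metric", "geographic_degrees")),
    precip_mode = match.arg(gv(cfg$precip_mode, "relative"),
                            c("relative", "additive")),
    reg_weight = gv(cfg$sdm$reg_weight, 0.01),
    background_n = gv(cfg$sdm$background_n, 10000),
    log_level = gv(cfg$log_level, "info")
  ), class = "run_config")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key '", unknown[1], "' in ", where)
  invisible(TRUE)
}

#' Run the full uncertainty pipeline from a configuration
#'
#' Reads the climate stack, occurrences, optional error surfaces and
#' delta stacks named in the config, runs every requested uncertainty
#' source over the scenario matrix, writes one probability raster per
#' (source, scenario) named `{species}_{source}_{scenario}.{ext}` plus a
#' JSON run manifest (config snapshot, master seed, replicate-failure
#' log, package version), and returns the maps invisibly. Reruns with
#' the same config are bit-identical.
#'
#' @param config a `run_config`, a config list, or a YAML path.
#' @return Invisibly, a nested list of
#'   `presence_probability_map`s, `maps[[source]][[scenario]]`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  p <- config$paths
  if (is.null(p$climate_dir) || is.null(p$occurrences) || is.null(p$output_dir))
    stop("config paths must name climate_dir, occurrences and output_dir")
  for (f in c(p$climate_dir, p$occurrences))
    if (!file.exists(f)) stop("input not found: ", f)

  climate <- read_climate_stack(p$climate_dir, config$raster_format,
                                config$crs_kind)
  region <- region_layer(climate)
  occ <- read_occurrences(p$occurrences, climate$geometry, region)
  errors <- if (!is.null(p$errors_dir))
    read_error_surfaces(p$errors_dir, config$raster_format, config$crs_kind)
  else NULL
  deltas <- if (!is.null(p$deltas_dir))
    read_delta_dir(p$deltas_dir, config$raster_format, config$crs_kind,
                   config$precip_mode)
  else list()

  dir.create(p$output_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (config$raster_format == "geotiff") "tif" else "asc"
  all_maps <- list()
  failures <- list()
  for (src in config$sources) {
    maps <- run_scenario_matrix(occ, climate, errors, deltas,
                                config$perturbations, src,
                                rule = config$rule,
                                background_n = config$background_n,
                                reg_weight = config$reg_weight)
    for (lab in names(maps))
      write_raster(maps[[lab]]$grid,
                   file.path(p$output_dir,
                             sprintf("%s_%s_%s.%s", config$species, src, lab,
                                     ext)),
                   config$raster_format)
    failures[[src]] <- attr(maps, "failures")
    all_maps[[src]] <- maps
  }
  manifest <- list(
    species = config$species,
    sources = config$sources,
    scenarios = names(all_maps[[1]]),
    master_seed = config$perturbations$master_seed,
    n_replicates = config$perturbations$n_replicates,
    failures = failures,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("sdmuncert")))
  jsonlite::write_json(manifest, file.path(p$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(all_maps)
}

# FNV-1a hash of the canonical YAML form of the config (hex string)
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass_deep(config))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b)) +
      (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

read_delta_dir <- function(dir, format, crs_kind, precip_mode) {
  subs <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (sub in subs) {
    st <- read_var_arrays(sub, format, crs_kind)
    meta_path <- file.path(sub, "delta.yaml")
    meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
    gv <- function(x, default) if (is.null(x)) default else x
    out[[length(out) + 1]] <- delta_stack(
      st$geometry, st$tmin, st$tmax, st$prec,
      gcm_id = gv(meta$gcm_id, basename(sub)),
      scenario_id = gv(meta$scenario_id, "custom"),
      target_year = gv(meta$target_year, 2085),
      precip_mode = gv(meta$precip_mode, precip_mode))
  }
  out
}
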