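# Monte Carlo orchestration on a small fixture: replicate counts are
# reduced relative to a production run but the mechanics are identical.

mc_fixture <- new.env()
mc_fx <- function() {
  if (is.null(mc_fixture$fx)) {
    mc_fixture$fx <- synth_fixture(n_rows = 40, n_cols = 40,
                                   n_occurrences = 150, rng_seed = 21)
    mc_fixture$bg <- sample_background(
      grid_layer(mc_fixture$fx$climate$geometry,
                 ifelse(mc_fixture$fx$climate$mask, NA_real_, 1)),
      800, rng_seed = 99)
  }
  list(fx = mc_fixture$fx, bg = mc_fixture$bg)
}

test_that("aggregation equals a per-cell counting oracle", {
  geom <- tiny_geom(4, 4, cell = 10)
  set.seed(31)
  maps <- lapply(1:7, function(i) {
    v <- matrix(rbinom(16, 1, 0.5), 4, 4)
    v[1, 1] <- NA
    grid_layer(geom, v)
  })
  agg <- aggregate_presence_probability(maps)
  expect_equal(agg$n_replicates, 7)
  for (i in 1:4) for (j in 1:4) {
    vals <- vapply(maps, function(m) m$values[i, j], numeric(1))
    if (anyNA(vals)) expect_true(is.na(agg$grid$values[i, j]))
    else expect_equal(agg$grid$values[i, j], sum(vals) / 7)
  }
  # all-identical maps give values in {0, 1}
  same <- aggregate_presence_probability(rep(maps[2], 5))
  expect_true(all(same$grid$values %in% c(0, 1) | is.na(same$grid$values)))
  # half presence -> 0.5
  half <- aggregate_presence_probability(c(
    rep(list(grid_layer(geom, 1)), 2), rep(list(grid_layer(geom, 0)), 2)))
  expect_true(all(half$grid$values == 0.5))
  expect_error(aggregate_presence_probability(list(
    grid_layer(geom, 1), grid_layer(tiny_geom(4, 4, cell = 20), 1))),
    "aligned")
})

test_that("baseline is a single binary map and zero-noise equals baseline", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 4, master_seed = 5)
  base <- run_source(f$fx$occurrences, f$fx$climate, cfg = cfg,
                     source = "baseline", background = f$bg)
  expect_true(all(base$grid$values %in% c(0, 1) | is.na(base$grid$values)))
  expect_equal(base$n_replicates, 1)

  cfg0 <- perturbation_config(locational_mean_km = 0, n_replicates = 4,
                              master_seed = 5)
  loc0 <- run_source(f$fx$occurrences, f$fx$climate, cfg = cfg0,
                     source = "locational", background = f$bg)
  expect_identical(is.na(loc0$grid$values), is.na(base$grid$values))
  expect_identical(loc0$grid$values[!is.na(loc0$grid$values)],
                   base$grid$values[!is.na(base$grid$values)])

  zero_err <- error_surface_set(f$fx$climate$geometry,
                                f$fx$errors$tmin * 0, f$fx$errors$tmax * 0,
                                f$fx$errors$prec * 0)
  cli0 <- run_source(f$fx$occurrences, f$fx$climate, zero_err, cfg0,
                     source = "climate_error", background = f$bg)
  expect_identical(cli0$grid$values[!is.na(cli0$grid$values)],
                   base$grid$values[!is.na(base$grid$values)])
})

test_that("probability values are multiples of 1/n_replicates", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 8, master_seed = 31)
  maps <- run_scenario_matrix(f$fx$occurrences, f$fx$climate, f$fx$errors,
                              list(), cfg, "locational", background = f$bg)
  p <- maps$current$grid$values
  expect_equal(maps$current$n_replicates, 8)
  expect_true(all(abs(p * 8 - round(p * 8)) < 1e-12, na.rm = TRUE))
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
})

test_that("runs are deterministic given the master seed", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 3, master_seed = 77)
  m1 <- run_source(f$fx$occurrences, f$fx$climate, f$fx$errors, cfg,
                   source = "combined", background = f$bg)
  m2 <- run_source(f$fx$occurrences, f$fx$climate, f$fx$errors, cfg,
                   source = "combined", background = f$bg)
  expect_identical(m1$grid$values, m2$grid$values)
})

test_that("the scenario matrix yields one map per scenario, fit once per replicate", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 2, master_seed = 13)
  maps <- run_scenario_matrix(f$fx$occurrences, f$fx$climate, f$fx$errors,
                              f$fx$deltas, cfg, "locational",
                              background = f$bg)
  expect_length(maps, 13)  # current + 6 GCMs x 2 scenarios
  expect_equal(names(maps)[1], "current")

  # a zero-magnitude delta reproduces the current map replicate for
  # replicate (identity-delta oracle)
  dims <- c(40, 40, 12)
  zero_delta <- delta_stack(f$fx$climate$geometry, array(0, dims),
                            array(0, dims), array(1, dims),
                            gcm_id = "null", scenario_id = "A2",
                            precip_mode = "relative")
  maps0 <- run_scenario_matrix(f$fx$occurrences, f$fx$climate, f$fx$errors,
                               list(zero_delta), cfg, "locational",
                               background = f$bg)
  expect_length(maps0, 2)
  expect_identical(maps0$current$grid$values, maps0$null_A2$grid$values)

  expect_error(run_scenario_matrix(f$fx$occurrences, f$fx$climate,
                                   f$fx$errors, list(zero_delta, zero_delta),
                                   cfg, "baseline", background = f$bg),
               "duplicate")
})

test_that("empty delta list yields a single current map", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 1, master_seed = 3)
  maps <- run_scenario_matrix(f$fx$occurrences, f$fx$climate, cfg = cfg,
                              source = "baseline", background = f$bg)
  expect_length(maps, 1)
  expect_named(maps, "current")
})

test_that("model variance runs one replicate per held-out segment", {
  f <- mc_fx()
  cfg <- perturbation_config(cv_segments = 10, master_seed = 41)
  src <- source_spec("model_variance", cfg)
  expect_equal(src$n_replicates, 10)
  maps <- run_scenario_matrix(f$fx$occurrences, f$fx$climate, cfg = cfg,
                              source = "model_variance", background = f$bg)
  p <- maps$current$grid$values
  expect_true(all(abs(p * 10 - round(p * 10)) < 1e-12, na.rm = TRUE))
})

test_that("failing replicates beyond 20% abort with a diagnostic", {
  f <- mc_fx()
  # an occurrence set with barely enough records: the combined source's
  # subsampling + split drops below the 5-presence floor in every
  # replicate
  few <- f$fx$occurrences
  few$records <- few$records[1:6, ]
  cfg <- perturbation_config(n_replicates = 4, master_seed = 1,
                             subsample_fraction = 0.4,
                             combined_train_fraction = 0.6)
  expect_error(
    suppressWarnings(run_source(few, f$fx$climate, f$fx$errors, cfg,
                                source = "combined", background = f$bg)),
    "failed replicates")
})

test_that("combined source requires error surfaces", {
  f <- mc_fx()
  cfg <- perturbation_config(n_replicates = 2)
  expect_error(run_source(f$fx$occurrences, f$fx$climate, NULL, cfg,
                          source = "combined", background = f$bg),
               "error surfaces")
})
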