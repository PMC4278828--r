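make_points <- function(n, geom, seed = 1) {
  set.seed(seed)
  occurrence_set(data.frame(
    id = sprintf("r%04d", seq_len(n)),
    x = runif(n, geom$x_origin + 1, geom$x_origin + geom$n_cols * geom$cell_size - 1),
    y = runif(n, geom$y_origin - geom$n_rows * geom$cell_size + 1,
              geom$y_origin - 1)), geom)
}

test_that("location perturbation calibrates the mean displacement", {
  # huge metric grid so nothing is redrawn at the boundary
  geom <- grid_geometry(1000, 1000, -500000, 500000, 1000)
  occ <- occurrence_set(data.frame(id = sprintf("p%05d", 1:20000),
                                   x = rep(0, 20000), y = rep(0, 20000)),
                        geom)
  pert <- perturb_locations(occ, mean_km = 10, rng_seed = 77)
  d_km <- sqrt(pert$records$x^2 + pert$records$y^2) / 1000
  expect_equal(mean(d_km), 10, tolerance = 0.02)

  # closed-form Rayleigh oracle for the displacement magnitudes
  sigma <- 10 / sqrt(pi / 2)
  ks <- suppressWarnings(stats::ks.test(d_km, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)

  # identity at zero magnitude; determinism per seed
  expect_identical(perturb_locations(occ, 0, rng_seed = 5)$records, occ$records)
  p1 <- perturb_locations(occ, 10, rng_seed = 5)
  p2 <- perturb_locations(occ, 10, rng_seed = 5)
  expect_identical(p1$records, p2$records)
})

test_that("alternative sigma calibrations are honoured", {
  geom <- grid_geometry(600, 600, -300000, 300000, 1000)
  occ <- occurrence_set(data.frame(id = sprintf("p%05d", 1:30000),
                                   x = rep(0, 30000), y = rep(0, 30000)), geom)
  p_sig <- perturb_locations(occ, 10, rng_seed = 3, calibration = "sigma")
  expect_equal(sd(p_sig$records$x) / 1000, 10, tolerance = 0.02)
  p_abs <- perturb_locations(occ, 10, rng_seed = 4,
                             calibration = "mean_abs_axis")
  expect_equal(mean(abs(p_abs$records$x)) / 1000, 10, tolerance = 0.02)
})

test_that("geographic grids scale the east-west noise by cos(latitude)", {
  geom <- grid_geometry(400, 400, 140, -30, 0.05, "geographic_degrees")
  lat <- -40
  occ <- occurrence_set(data.frame(id = sprintf("p%05d", 1:20000),
                                   x = rep(150, 20000), y = rep(lat, 20000)),
                        geom)
  pert <- perturb_locations(occ, 10, rng_seed = 6)
  dx_km <- (pert$records$x - 150) * 111.19 * cos(lat * pi / 180)
  dy_km <- (pert$records$y - lat) * 111.19
  d_km <- sqrt(dx_km^2 + dy_km^2)
  expect_equal(mean(d_km), 10, tolerance = 0.02)
})

test_that("points perturbed onto masked cells are redrawn", {
  geom <- tiny_geom(20, 20, cell = 1000)
  v <- matrix(1, 20, 20); v[, 11:20] <- NA   # east half is sea
  region <- grid_layer(geom, v)
  occ <- occurrence_set(data.frame(id = sprintf("p%03d", 1:200),
                                   x = rep(9500, 200),
                                   y = seq(500, 19500, length.out = 200)),
                        geom)
  pert <- perturb_locations(occ, 2, rng_seed = 9, region = region)
  idx <- point_to_cell(geom, pert$records$x, pert$records$y)
  expect_true(all(!is.na(idx$row)))
  expect_true(all(!is.na(region$values[cbind(idx$row, idx$col)])))
})

test_that("biased subsample removes the farthest records (sort oracle)", {
  geom <- tiny_geom(10, 10, cell = 1000)
  occ <- make_points(200, geom, seed = 2)
  kept <- biased_subsample(occ, 0.10, rng_seed = 41)
  expect_equal(n_occurrences(kept), 180)

  # reproduce the anchor with the same seed and check against a full sort
  anchor <- sdmuncert:::with_seed(41, sdmuncert:::random_region_point(geom, NULL))
  d <- sqrt((occ$records$x - anchor$x)^2 + (occ$records$y - anchor$y)^2)
  oracle_kept <- occ$records$id[order(d)][1:180]
  expect_setequal(kept$records$id, oracle_kept)

  # fraction -> 0 removes exactly the single farthest record
  kept1 <- biased_subsample(occ, 1e-9, rng_seed = 41)
  expect_equal(n_occurrences(kept1), 199)
  expect_false(occ$records$id[which.max(d)] %in% kept1$records$id)
})

test_that("collinear points lose their far tail under biased subsampling", {
  geom <- grid_geometry(1, 100, 0, 1, 1)
  occ <- occurrence_set(data.frame(id = sprintf("c%03d", 1:100),
                                   x = seq_len(100) - 0.5, y = rep(0.5, 100)),
                        geom)
  # find a seed whose anchor lands in the west fifth of the line
  seed <- NULL
  for (s in 1:50) {
    a <- sdmuncert:::with_seed(s, sdmuncert:::random_region_point(geom, NULL))
    if (a$x < 20) { seed <- s; break }
  }
  expect_false(is.null(seed))
  kept <- biased_subsample(occ, 0.10, rng_seed = seed)
  expect_setequal(setdiff(occ$records$id, kept$records$id),
                  sprintf("c%03d", 91:100))
})

test_that("random subsample sizes, determinism and removal frequencies", {
  geom <- tiny_geom(10, 10, cell = 1000)
  occ <- make_points(200, geom, seed = 3)
  kept <- random_subsample(occ, 0.10, rng_seed = 1)
  expect_equal(n_occurrences(kept), 180)
  expect_identical(random_subsample(occ, 0.10, rng_seed = 1)$records,
                   kept$records)
  expect_error(random_subsample(occ, 0.999, rng_seed = 1), "every record")

  # hypergeometric oracle on a smaller set: each record removed with
  # probability fraction
  occ40 <- make_points(40, geom, seed = 4)
  removed <- integer(40)
  n_rep <- 4000
  for (s in seq_len(n_rep)) {
    k <- random_subsample(occ40, 0.10, rng_seed = s)
    removed <- removed + !(occ40$records$id %in% k$records$id)
  }
  p <- 4 / 40
  se <- sqrt(p * (1 - p) / n_rep)
  expect_true(all(abs(removed / n_rep - p) < 4 * se))
})

test_that("cross-validation segments partition the records evenly", {
  geom <- tiny_geom(10, 10, cell = 1000)
  occ1000 <- make_points(1000, geom, seed = 5)
  seg <- cv_segments(occ1000, 100, rng_seed = 1)
  expect_length(seg, 100)
  expect_true(all(lengths(seg) == 10))
  expect_setequal(unlist(seg), occ1000$records$id)

  occ1003 <- make_points(1003, geom, seed = 6)
  seg2 <- cv_segments(occ1003, 100, rng_seed = 2)
  expect_equal(sort(unique(lengths(seg2))), c(10, 11))
  expect_equal(sum(lengths(seg2) == 11), 3)
  expect_equal(length(unlist(seg2)), 1003)
  expect_equal(anyDuplicated(unlist(seg2)), 0)

  occ10 <- make_points(10, geom, seed = 7)
  loo <- cv_segments(occ10, 10, rng_seed = 3)
  expect_true(all(lengths(loo) == 1))
  expect_error(cv_segments(occ10, 11, rng_seed = 1), "segments")
})

test_that("bootstrap splits are disjoint, exhaustive, and overlap across seeds", {
  geom <- tiny_geom(10, 10, cell = 1000)
  occ <- make_points(1000, geom, seed = 8)
  sp <- bootstrap_split(occ, 0.99, rng_seed = 1)
  expect_equal(n_occurrences(sp$train), 990)
  expect_equal(n_occurrences(sp$test), 10)
  expect_length(intersect(sp$train$records$id, sp$test$records$id), 0)
  expect_setequal(c(sp$train$records$id, sp$test$records$id),
                  occ$records$id)
  # testing sets from different replicates may overlap
  tests <- lapply(1:40, function(s)
    bootstrap_split(occ, 0.9, rng_seed = s)$test$records$id)
  overlaps <- vapply(2:40, function(i)
    length(intersect(tests[[1]], tests[[i]])), integer(1))
  expect_gt(sum(overlaps), 0)
})

test_that("climate error simulation: identity at zero SD, node-level SD", {
  fxg <- tiny_geom(30, 30, cell = 1000)
  dims <- c(30, 30, 12)
  st <- climate_stack(fxg, array(5, dims), array(15, dims), array(60, dims))
  zero <- error_surface_set(fxg, array(0, dims), array(0, dims), array(0, dims))
  cfg <- perturbation_config(coarse_spacing_temp = 10000,
                             coarse_spacing_prec = 5000)
  out0 <- simulate_climate_error(st, zero, cfg, rng_seed = 1)
  expect_identical(out0$tmin, st$tmin)
  expect_identical(out0$tmax, st$tmax)
  expect_identical(out0$prec, st$prec)

  # per-node SD oracle: at fine cells at coarse nodes the perturbation SD
  # equals the error-surface value (tmax month 1, SD 0.8 C; other layers
  # zero so only this noise field is drawn)
  etmax <- array(0, dims); etmax[, , 1] <- 0.8
  errs <- error_surface_set(fxg, array(0, dims), etmax, array(0, dims))
  # coarse nodes: spacing 10 cells starting one spacing before origin;
  # node centres at x = -5000, 5000, 15000, ... -> cells 6, 16, 26
  node_cells <- expand.grid(row = c(6, 16, 26), col = c(6, 16, 26))
  samples <- matrix(NA_real_, 500, nrow(node_cells))
  for (r in 1:500) {
    out <- simulate_climate_error(st, errs, cfg, rng_seed = r)
    dev <- out$tmax[, , 1] - st$tmax[, , 1]
    samples[r, ] <- dev[cbind(node_cells$row, node_cells$col)]
  }
  sds <- apply(samples, 2, sd)
  expect_true(all(abs(sds - 0.8) / 0.8 < 0.15))
  expect_lt(mean(abs(colMeans(samples))), 0.15)
})

test_that("the 36 monthly noise fields are mutually independent streams", {
  fxg <- tiny_geom(12, 12, cell = 1000)
  dims <- c(12, 12, 12)
  st <- climate_stack(fxg, array(5, dims), array(15, dims), array(60, dims))
  errs <- error_surface_set(fxg, array(1, dims), array(1, dims),
                            array(1, dims))
  cfg <- perturbation_config(coarse_spacing_temp = 4000,
                             coarse_spacing_prec = 4000)
  out <- simulate_climate_error(st, errs, cfg, rng_seed = 2)
  devs <- cbind(sapply(1:12, function(m) as.vector(out$tmin[, , m] - st$tmin[, , m])),
                sapply(1:12, function(m) as.vector(out$tmax[, , m] - st$tmax[, , m])),
                sapply(1:12, function(m) as.vector(out$prec[, , m] - st$prec[, , m])))
  # no two of the 36 deviation fields identical, none degenerate
  expect_equal(ncol(devs), 36)
  cors <- stats::cor(devs)
  off_diag <- cors[upper.tri(cors)]
  expect_true(all(abs(off_diag) < 0.9))
  expect_true(all(apply(devs, 2, sd) > 0))

  # same seed reproduces the same perturbation exactly
  out2 <- simulate_climate_error(st, errs, cfg, rng_seed = 2)
  expect_identical(out$tmax, out2$tmax)
  expect_error(simulate_climate_error(st, errs,
                                      perturbation_config(coarse_spacing_temp = 500,
                                                          coarse_spacing_prec = 500),
                                      rng_seed = 1),
               "spacing")
})

test_that("climate-error noise is smooth below the coarse spacing", {
  fxg <- tiny_geom(60, 60, cell = 1000)
  dims <- c(60, 60, 12)
  st <- climate_stack(fxg, array(5, dims), array(15, dims), array(60, dims))
  etmax <- array(0, dims); etmax[, , 1] <- 1
  errs <- error_surface_set(fxg, array(0, dims), etmax, array(0, dims))
  cfg <- perturbation_config(coarse_spacing_temp = 12000,
                             coarse_spacing_prec = 12000)
  lag1 <- node_cors <- numeric(30)
  for (r in 1:30) {
    out <- simulate_climate_error(st, errs, cfg, rng_seed = 100 + r)
    noise <- out$tmax[, , 1] - st$tmax[, , 1]
    lag1[r] <- stats::cor(as.vector(noise[, -1]), as.vector(noise[, -60]))
  }
  expect_gt(mean(lag1), 0.9)

  # noise at nodes >= 2 coarse spacings apart is uncorrelated within
  # sampling error (node cells 6 and 30: 24 cells = 2 spacings apart)
  pairs <- sapply(1:200, function(r) {
    out <- simulate_climate_error(st, errs, cfg, rng_seed = 500 + r)
    noise <- out$tmax[, , 1] - st$tmax[, , 1]
    c(noise[6, 6], noise[6, 30])
  })
  expect_lt(abs(stats::cor(pairs[1, ], pairs[2, ])), 3 / sqrt(200))
})

test_that("biased loss removes more spatially clustered mass than random loss", {
  # retained points after biased removal should sit closer together on
  # average (a whole geographic tail is cut) than after random removal
  fx <- shared_fixture()
  occ <- fx$occurrences
  mean_nn <- function(o) {
    d <- as.matrix(stats::dist(cbind(o$records$x, o$records$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn_bias <- nn_rand <- numeric(200)
  for (s in 1:200) {
    nn_bias[s] <- mean_nn(biased_subsample(occ, 0.10, rng_seed = s))
    nn_rand[s] <- mean_nn(random_subsample(occ, 0.10, rng_seed = s))
  }
  tt <- stats::t.test(nn_bias, nn_rand)
  expect_lt(tt$p.value, 0.001)
  expect_lt(mean(nn_bias), mean(nn_rand))
})

test_that("zero-magnitude settings reduce every perturbation to the identity", {
  fx <- shared_fixture()
  occ <- fx$occurrences
  expect_identical(perturb_locations(occ, 0, rng_seed = 3)$records,
                   occ$records)
  zero_err <- error_surface_set(
    fx$climate$geometry,
    fx$errors$tmin * 0, fx$errors$tmax * 0, fx$errors$prec * 0)
  out <- simulate_climate_error(fx$climate, zero_err,
                                perturbation_config(), rng_seed = 5)
  expect_identical(out$tmin, fx$climate$tmin)
  expect_identical(out$prec, fx$climate$prec)
})
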