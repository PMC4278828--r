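test_that("background sampling is uniform, exhaustive and reproducible", {
  geom <- tiny_geom(4, 5, cell = 10)
  v <- matrix(1, 4, 5); v[1, ] <- NA
  region <- grid_layer(geom, v)
  n_open <- sum(!is.na(v))

  all_cells <- sample_background(region, n_open, rng_seed = 3)
  expect_equal(n_occurrences(all_cells), n_open)
  expect_equal(anyDuplicated(paste(all_cells$records$x, all_cells$records$y)), 0)

  a <- sample_background(region, 7, rng_seed = 12)
  b <- sample_background(region, 7, rng_seed = 12)
  expect_identical(a$records[, c("x", "y")], b$records[, c("x", "y")])
  expect_error(sample_background(region, n_open + 1, rng_seed = 1), "replace")

  # multinomial oracle: n = 1 draws, each open cell hit ~ uniformly
  draws <- vapply(1:10000, function(s) {
    r <- sample_background(region, 1, rng_seed = s)$records
    paste(r$x, r$y)
  }, character(1))
  freq <- table(draws)
  expect_equal(length(freq), n_open)
  p <- 1 / n_open
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq / 10000 - p) < 3.5 * se + 1e-9))
})

test_that("separable classes give a positive coefficient and monotone prediction", {
  fx <- shared_fixture()
  bio <- fx$bioclim
  # presences at the warmest cells, background at the coldest: the
  # annual_mean_temp coefficient must be positive and suitability
  # monotone in it
  amt <- bio$layers$annual_mean_temp
  ord <- order(amt, na.last = NA)
  geom <- bio$geometry
  cc <- cell_centers(geom)
  cell_xy <- function(cells) {
    data.frame(id = paste0("r", seq_along(cells)),
               x = cc$x[(cells - 1) %/% geom$n_rows + 1],
               y = cc$y[(cells - 1) %% geom$n_rows + 1])
  }
  pres <- occurrence_set(cell_xy(tail(ord, 60)), geom)
  bg <- occurrence_set(cell_xy(head(ord, 400)), geom)
  fit <- fit_sdm(pres, bg, bio, reg_weight = 0.01,
                 variables = "annual_mean_temp")
  expect_gt(coef(fit)[["annual_mean_temp"]], 0)
  rng <- range(amt, na.rm = TRUE)
  s <- predict(fit, data.frame(annual_mean_temp = seq(rng[1], rng[2],
                                                      length.out = 7)))
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(s[7], s[1])
})

test_that("prediction agrees with direct evaluation of the logistic formula", {
  fx <- shared_fixture()
  fit <- fit_sdm(fx$occurrences,
                 sample_background(landscape_region(fx), 1000, rng_seed = 4),
                 fx$bioclim)
  suit <- predict_suitability(fit, fx$bioclim)
  expect_true(all(suit$values >= 0 & suit$values <= 1, na.rm = TRUE))
  expect_identical(is.na(suit$values), is.na(fx$bioclim$layers[[1]]))

  # closed-form oracle at 10 random unmasked cells
  set.seed(8)
  cells <- sample(which(!is.na(suit$values)), 10)
  raw <- sapply(bioclim_names(), function(nm) fx$bioclim$layers[[nm]][cells])
  ctr <- fit$feature_spec$centers; scl <- fit$feature_spec$scales
  z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  eta <- fit$intercept +
    as.numeric(cbind(z, z^2) %*% c(fit$coefficients))
  expect_lt(max(abs(suit$values[cells] - 1 / (1 + exp(-eta)))), 1e-9)
})

test_that("all-zero model predicts uniform 0.5", {
  fx <- shared_fixture()
  fit <- fit_sdm(fx$occurrences,
                 sample_background(landscape_region(fx), 500, rng_seed = 2),
                 fx$bioclim)
  fit$coefficients[] <- 0
  fit$intercept <- 0
  suit <- predict_suitability(fit, fx$bioclim)
  expect_equal(unique(as.vector(suit$values[!is.na(suit$values)])), 0.5)
})

test_that("duplicating presences leaves the fit unchanged (class weighting)", {
  fx <- shared_fixture()
  bg <- sample_background(landscape_region(fx), 800, rng_seed = 6)
  occ <- fx$occurrences
  dup <- occ
  extra <- occ$records
  extra$id <- paste0(extra$id, "_dup")
  dup$records <- rbind(occ$records, extra)
  f1 <- fit_sdm(occ, bg, fx$bioclim)
  f2 <- fit_sdm(dup, bg, fx$bioclim)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-5)
})

test_that("near-zero ridge matches an unpenalized glm oracle", {
  fx <- shared_fixture()
  bg <- sample_background(landscape_region(fx), 600, rng_seed = 9)
  fit <- fit_sdm(fx$occurrences, bg, fx$bioclim, reg_weight = 1e-9)
  # independent route: stats::glm on the identical standardized design
  raw_p <- sapply(bioclim_names(), function(nm)
    sdmuncert:::extract_at_points(bioclim_layer(fx$bioclim, nm),
                                  fx$occurrences$records$x,
                                  fx$occurrences$records$y))
  raw_b <- sapply(bioclim_names(), function(nm)
    sdmuncert:::extract_at_points(bioclim_layer(fx$bioclim, nm),
                                  bg$records$x, bg$records$y))
  raw <- rbind(raw_p, raw_b)
  z <- sweep(sweep(raw, 2, fit$feature_spec$centers), 2,
             fit$feature_spec$scales, "/")
  X <- cbind(z, z^2)
  y <- c(rep(1, nrow(raw_p)), rep(0, nrow(raw_b)))
  w <- c(rep(0.5 / nrow(raw_p), nrow(raw_p)),
         rep(0.5 / nrow(raw_b), nrow(raw_b)))
  ref <- suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = w,
                                         family = stats::binomial()))
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - ref$coefficients)),
            0.01)
})

test_that("increasing the ridge weight weakly shrinks the coefficients", {
  fx <- shared_fixture()
  bg <- sample_background(landscape_region(fx), 800, rng_seed = 13)
  norms <- vapply(c(1e-4, 1e-2, 1e-1, 1, 10), function(lam)
    sqrt(sum(fit_sdm(fx$occurrences, bg, fx$bioclim, reg_weight = lam)$
               coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("degenerate inputs error as specified", {
  fx <- shared_fixture()
  bg <- sample_background(landscape_region(fx), 100, rng_seed = 2)
  few <- fx$occurrences
  few$records <- few$records[1:4, ]
  expect_error(fit_sdm(few, bg, fx$bioclim), "at least 5")
  fit <- fit_sdm(fx$occurrences, bg, fx$bioclim)
  bad <- fx$bioclim
  bad$layers$annual_precip <- NULL
  expect_error(predict(fit, bad), "annual_precip")
})

test_that("max sens+spec threshold matches the 4-candidate brute force", {
  geom <- tiny_geom(2, 2, cell = 10)
  suit <- grid_layer(geom, matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2))
  cc <- cell_centers(geom)
  pres <- occurrence_set(data.frame(id = c("p1", "p2"),
                                    x = cc$x[c(1, 2)], y = cc$y[c(1, 1)]), geom)
  bg <- occurrence_set(data.frame(id = c("b1", "b2"),
                                  x = cc$x[c(1, 2)], y = cc$y[c(2, 2)]), geom)
  # presences at 0.9, 0.8; background at 0.1, 0.2; any threshold in
  # (0.2, 0.8] is perfect and the lowest candidate achieving it is 0.8
  thr <- compute_threshold(NULL, pres, bg, suit)
  expect_equal(thr, 0.8)
})

test_that("fixed and percentile threshold rules follow their conventions", {
  geom <- grid_geometry(1, 10, 0, 1, 1)
  suit <- grid_layer(geom, matrix(seq(0.1, 1.0, by = 0.1), 1, 10))
  pres <- occurrence_set(data.frame(id = paste0("p", 1:10),
                                    x = seq_len(10) - 0.5, y = rep(0.5, 10)),
                         geom)
  expect_equal(compute_threshold(NULL, pres, NULL, suit,
                                 threshold_rule("fixed_value", 0.5)), 0.5)
  # nearest-rank oracle: sorted values, rank = ceiling(p/100 * n)
  for (p in c(10, 25, 50, 95)) {
    got <- compute_threshold(NULL, pres, NULL, suit,
                             threshold_rule("training_presence_percentile", p))
    expect_equal(got, sort(seq(0.1, 1.0, 0.1))[ceiling(p / 100 * 10)])
  }
  expect_error(threshold_rule("fixed_value", 1.2), "0, 1")
})

test_that("degenerate suitability falls back to 0.5 with a warning", {
  geom <- tiny_geom(2, 2, cell = 10)
  suit <- grid_layer(geom, matrix(0.3, 2, 2))
  cc <- cell_centers(geom)
  pres <- occurrence_set(data.frame(id = "p", x = cc$x[1], y = cc$y[1]), geom)
  bg <- occurrence_set(data.frame(id = "b", x = cc$x[2], y = cc$y[2]), geom)
  expect_warning(thr <- compute_threshold(NULL, pres, bg, suit), "degenerate")
  expect_equal(thr, 0.5)
})

test_that("thresholding uses >= and keeps masks", {
  geom <- tiny_geom(2, 2, cell = 10)
  suit <- grid_layer(geom, matrix(c(0.7, 0.5, 0.49999, NA), 2, 2))
  bin <- threshold_map(suit, 0.5)
  expect_equal(bin$values[1, 1], 1)
  expect_equal(bin$values[2, 1], 1)   # exactly at the threshold -> presence
  expect_equal(bin$values[1, 2], 0)
  expect_true(is.na(bin$values[2, 2]))
  uni <- threshold_map(grid_layer(geom, 0.7), 0.5)
  expect_true(all(uni$values == 1))
})
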