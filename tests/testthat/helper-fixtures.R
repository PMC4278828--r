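# Shared fixtures, built once per test run. Sizes are kept small so the
# whole suite runs quickly on one CPU; the statistical checks scale their
# replicate counts accordingly.

tiny_geom <- function(nr = 5, nc = 5, cell = 1000, crs = "projected_metric") {
  grid_geometry(nr, nc, 0, nr * cell, cell, crs)
}

# random unmasked climate stack on a tiny grid (no mask) for oracle checks
random_stack <- function(nr = 5, nc = 5, seed = 1) {
  set.seed(seed)
  dims <- c(nr, nc, 12)
  tmean <- array(stats::rnorm(prod(dims), 10, 5), dims)
  dr <- array(stats::runif(prod(dims), 2, 10), dims)
  prec <- array(stats::rexp(prod(dims), 1 / 60), dims)
  climate_stack(tiny_geom(nr, nc), tmean - dr / 2, tmean + dr / 2, prec)
}

# default shared landscape fixture (modest size; used by the model and
# Monte Carlo tests)
fixture_cache <- new.env()
shared_fixture <- function() {
  if (is.null(fixture_cache$fx))
    fixture_cache$fx <- synth_fixture(n_rows = 60, n_cols = 60,
                                      n_occurrences = 300, rng_seed = 11)
  fixture_cache$fx
}

# full-size study fixture (100 x 100 km landscape, 300 records) with its
# once-sampled background, for the end-to-end acceptance checks
acc_fixture <- function() {
  if (is.null(fixture_cache$acc)) {
    fx <- synth_fixture(rng_seed = 11)
    region <- grid_layer(fx$climate$geometry,
                         ifelse(fx$climate$mask, NA_real_, 1))
    bg <- sample_background(region, min(10000, sum(!fx$climate$mask) - 1L),
                            rng_seed = 2)
    fixture_cache$acc <- list(fx = fx, bg = bg, region = region)
  }
  fixture_cache$acc
}

# brute-force per-cell bioclim oracle: exhaustive scan of the 12
# wrap-around windows, scalar code, no shared logic with derive_bioclim
bioclim_bruteforce <- function(stack) {
  nr <- stack$geometry$n_rows; nc <- stack$geometry$n_cols
  out <- list()
  for (nm in bioclim_names()) out[[nm]] <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tmin <- stack$tmin[i, j, ]; tmax <- stack$tmax[i, j, ]
    prec <- stack$prec[i, j, ]
    if (anyNA(tmin)) next
    tmean <- (tmin + tmax) / 2
    qt <- qp <- numeric(12)
    for (w in 1:12) {
      mo <- ((w - 1):(w + 1)) %% 12 + 1
      qt[w] <- mean(tmean[mo]); qp[w] <- sum(prec[mo])
    }
    warm <- which(qt == max(qt))[1]
    cold <- which(qt == min(qt))[1]
    out$annual_mean_temp[i, j] <- mean(tmean)
    out$min_temp_coldest_month[i, j] <- min(tmin)
    out$max_temp_warmest_month[i, j] <- max(tmax)
    out$annual_precip[i, j] <- sum(prec)
    out$precip_warmest_quarter[i, j] <- qp[warm]
    out$precip_coldest_quarter[i, j] <- qp[cold]
  }
  out
}
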