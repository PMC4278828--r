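#' Sample background (pseudo-absence) points
#'
#' Draws `n` background points at the centres of unmasked cells of the
#' study region, uniformly and by default without replacement.
#' Presence-background models contrast the environment at presences with
#' this sample of the available environment.
#'
#' @param region a `grid_layer` whose mask defines the study region.
#' @param n number of points (default 10000, the common MaxEnt
#'   convention), capped at the number of unmasked cells when sampling
#'   without replacement would otherwise fail is an error.
#' @param rng_seed integer seed; the draw is reproducible given the seed.
#' @param replace sample cells with replacement.
#' @return An [occurrence_set()] with ids `bg000001, ...`.
#' @export
sample_background <- function(region, n = 10000, rng_seed = 1, replace = FALSE) {
  stopifnot(inherits(region, "grid_layer"), n >= 1)
  cells <- which(!is.na(region$values))
  if (!replace && n > length(cells))
    stop("requested ", n, " background points but only ", length(cells),
         " unmasked cells are available (set replace = TRUE to allow reuse)")
  picked <- with_seed(rng_seed, {
    if (length(cells) == 1L) rep(cells, if (replace) n else 1L)
    else sample(cells, n, replace = replace)
  })
  geom <- region$geometry
  row <- (picked - 1) %% geom$n_rows + 1
  col <- (picked - 1) %/% geom$n_rows + 1
  cc <- cell_centers(geom)
  occurrence_set(data.frame(id = sprintf("bg%06d", seq_along(picked)),
                            x = cc$x[col], y = cc$y[row]),
                 geom)
}

#' Fit a presence-background suitability model
#'
#' The default backend is a ridge-penalized presence-background logistic
#' regression on standardized linear and quadratic transforms of the six
#' bioclimatic predictors — the minimal member of the MaxEnt model
#' family. Presence and background classes are weighted so that each
#' class contributes equal total weight regardless of record counts
#' (duplicating every presence leaves the fit unchanged up to solver
#' tolerance). The fit is deterministic given its inputs.
#'
#' Predictor values are extracted at the cell containing each point.
#' Records with non-finite predictor values are dropped; a predictor that
#' is constant over the training data is dropped with a warning.
#'
#' @param presences,background [occurrence_set()]s.
#' @param predictors a [derive_bioclim()] `bioclim_set` aligned with the
#'   study region.
#' @param reg_weight nonnegative ridge penalty weight (the lambda of the
#'   penalized likelihood). Larger values shrink coefficients towards
#'   zero.
#' @param rng_seed integer seed, part of the backend interface; the
#'   built-in backend is deterministic and ignores it.
#' @param variables which bioclim layers to use as predictors.
#' @return An object of class `sdm` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @examples
#' land <- generate_landscape(landscape_params(n_rows = 30, n_cols = 30))
#' bio <- derive_bioclim(land$climate)
#' occ <- generate_occurrences(default_niche(bio), bio, 80, rng_seed = 7)
#' bg <- sample_background(landscape_region(land), 500, rng_seed = 8)
#' fit <- fit_sdm(occ, bg, bio)
#' coef(fit)
#' @export
fit_sdm <- function(presences, background, predictors, reg_weight = 0.01,
                    rng_seed = 1, variables = bioclim_names()) {
  stopifnot(inherits(presences, "occurrence_set"),
            inherits(background, "occurrence_set"),
            inherits(predictors, "bioclim_set"), reg_weight >= 0)
  variables <- match.arg(variables, bioclim_names(), several.ok = TRUE)

  raw_p <- extract_bioclim(predictors, presences, variables)
  raw_b <- extract_bioclim(predictors, background, variables)
  ok_p <- stats::complete.cases(raw_p)
  ok_b <- stats::complete.cases(raw_b)
  raw_p <- raw_p[ok_p, , drop = FALSE]
  raw_b <- raw_b[ok_b, , drop = FALSE]
  np <- nrow(raw_p); nb <- nrow(raw_b)
  if (np < 5)
    stop("too few usable presences (", np, "); at least 5 are required")
  if (nb < 2) stop("too few usable background points")

  raw <- rbind(raw_p, raw_b)
  # class-weighted moments: presences and background contribute equal
  # total weight, so the standardization (like the fit) is invariant to
  # duplicating records within a class
  wts <- c(rep(0.5 / np, np), rep(0.5 / nb, nb))
  centers <- colSums(raw * wts)
  scales <- sqrt(colSums(sweep(raw, 2, centers)^2 * wts))
  const <- scales <= .Machine$double.eps^0.5 * pmax(1, abs(centers))
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(variables[const], collapse = ", "))
    variables <- variables[!const]
    if (length(variables) == 0) stop("no non-constant predictors remain")
    raw <- raw[, !const, drop = FALSE]
    centers <- centers[!const]
    scales <- scales[!const]
  }
  spec <- list(variables = variables, centers = centers, scales = scales)
  x <- design_matrix(spec, raw)
  y <- c(rep(1, np), rep(0, nb))
  w <- c(rep(0.5 / np, np), rep(0.5 / nb, nb))

  fit <- ridge_logistic(x, y, w, reg_weight)
  structure(list(
    backend_id = "ridge_logistic",
    feature_spec = spec,
    coefficients = fit$beta,
    intercept = fit$intercept,
    reg_weight = reg_weight,
    training = list(n_presence = np, n_background = nb,
                    training_threshold = NA_real_)
  ), class = "sdm")
}

# linear + quadratic standardized features from raw predictor values
design_matrix <- function(spec, raw) {
  z <- sweep(sweep(raw[, spec$variables, drop = FALSE], 2, spec$centers),
             2, spec$scales, "/")
  x <- cbind(z, z^2)
  colnames(x) <- c(spec$variables, paste0(spec$variables, "_sq"))
  x
}

extract_bioclim <- function(bioclim, occ, variables) {
  out <- sapply(variables, function(nm)
    extract_at_points(bioclim_layer(bioclim, nm), occ$records$x, occ$records$y))
  if (!is.matrix(out)) out <- matrix(out, nrow = n_occurrences(occ),
                                     dimnames = list(NULL, variables))
  out
}

# weighted ridge logistic regression; glmnet when >= 2 features, a small
# Newton solver for the single-feature edge case (same objective:
# average weighted negative log-likelihood + lambda/2 * ||beta||^2)
ridge_logistic <- function(x, y, w, lambda) {
  if (ncol(x) >= 2) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, weights = w, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-12, maxit = 1e6)
    beta <- as.numeric(fit$beta)
    names(beta) <- rownames(fit$beta)
    return(list(intercept = as.numeric(fit$a0), beta = beta))
  }
  wn <- w / sum(w)
  b <- c(0, 0) # intercept, slope
  X <- cbind(1, x[, 1])
  for (it in 1:100) {
    eta <- X %*% b
    p <- 1 / (1 + exp(-eta))
    grad <- crossprod(X, wn * (p - y)) + lambda * c(0, b[2])
    W <- wn * p * (1 - p)
    H <- crossprod(X, X * as.numeric(W)) + diag(c(1e-12, lambda))
    step <- solve(H, grad)
    b <- b - step
    if (max(abs(step)) < 1e-12) break
  }
  beta <- b[2]; names(beta) <- colnames(x)
  list(intercept = b[1], beta = beta)
}

#' @export
print.sdm <- function(x, ...) {
  cat(sprintf("<sdm> %s: %d presences vs %d background, ridge weight %g\n",
              x$backend_id, x$training$n_presence, x$training$n_background,
              x$reg_weight))
  cat("coefficients (standardized features):\n")
  print(round(x$coefficients, 4))
  if (is.finite(x$training$training_threshold))
    cat(sprintf("training threshold: %.4f\n", x$training$training_threshold))
  invisible(x)
}

#' @export
summary.sdm <- function(object, ...) {
  out <- list(backend = object$backend_id,
              coefficients = object$coefficients,
              intercept = object$intercept,
              reg_weight = object$reg_weight,
              training = object$training)
  class(out) <- "summary.sdm"
  out
}

#' @export
print.summary.sdm <- function(x, ...) {
  cat("Presence-background suitability model (", x$backend, ")\n", sep = "")
  cat(sprintf("  training: %d presences, %d background points\n",
              x$training$n_presence, x$training$n_background))
  cat(sprintf("  ridge penalty: %g\n", x$reg_weight))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.sdm <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict logistic habitat suitability
#'
#' @param object a fitted `sdm`.
#' @param newdata a `bioclim_set` (returns a suitability `grid_layer` in
#'   `[0, 1]`, masked wherever any predictor is masked) or a numeric
#'   matrix / data frame of raw predictor values with columns named after
#'   the model's variables (returns a numeric vector).
#' @param type `"response"` (logistic suitability) or `"link"`.
#' @param ... unused.
#' @export
predict.sdm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "bioclim_set")) {
    missing <- setdiff(object$feature_spec$variables, names(newdata$layers))
    if (length(missing))
      stop("missing predictor layer(s): ", paste(missing, collapse = ", "))
    raw <- sapply(object$feature_spec$variables,
                  function(nm) as.vector(newdata$layers[[nm]]))
    eta <- rep(NA_real_, nrow(raw))
    ok <- stats::complete.cases(raw)
    eta[ok] <- linear_predictor(object, raw[ok, , drop = FALSE])
    out <- if (type == "response") plogis(eta) else eta
    return(grid_layer(newdata$geometry,
                      matrix(out, newdata$geometry$n_rows,
                             newdata$geometry$n_cols)))
  }
  raw <- as.matrix(as.data.frame(newdata)[, object$feature_spec$variables,
                                          drop = FALSE])
  eta <- linear_predictor(object, raw)
  if (type == "response") plogis(eta) else eta
}

linear_predictor <- function(object, raw) {
  x <- design_matrix(object$feature_spec, raw)
  as.numeric(object$intercept + x[, names(object$coefficients), drop = FALSE] %*%
               object$coefficients)
}

#' @rdname predict.sdm
#' @param model a fitted `sdm`.
#' @param predictors a `bioclim_set`.
#' @export
predict_suitability <- function(model, predictors) {
  predict(model, predictors, type = "response")
}

#' Threshold rules for converting suitability to presence/absence
#'
#' @param rule_id one of `"max_sens_plus_spec"` (threshold maximizing
#'   sensitivity + specificity over the observed suitability values, ties
#'   resolved to the lowest candidate), `"fixed_value"`, or
#'   `"training_presence_percentile"` (nearest-rank percentile of the
#'   presence suitabilities).
#' @param parameter the fixed value in `(0, 1)` or the percentile in
#'   `[0, 100]`.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(rule_id = c("max_sens_plus_spec", "fixed_value",
                                       "training_presence_percentile"),
                           parameter = NA_real_) {
  rule_id <- match.arg(rule_id)
  if (rule_id == "fixed_value" &&
      !(is.finite(parameter) && parameter > 0 && parameter < 1))
    stop("fixed_value threshold parameter must lie in (0, 1)")
  if (rule_id == "training_presence_percentile" &&
      !(is.finite(parameter) && parameter >= 0 && parameter <= 100))
    stop("percentile parameter must lie in [0, 100]")
  structure(list(rule_id = rule_id, parameter = parameter),
            class = "threshold_rule")
}

#' Compute the presence/absence threshold of a fitted model
#'
#' @param model a fitted `sdm`.
#' @param presences,background training [occurrence_set()]s.
#' @param suitability the suitability `grid_layer` from
#'   [predict_suitability()].
#' @param rule a [threshold_rule()].
#' @return The threshold, a single number. If all observed suitabilities
#'   are equal the rule degenerates and 0.5 is returned with a warning.
#' @export
compute_threshold <- function(model, presences, background, suitability,
                              rule = threshold_rule("max_sens_plus_spec")) {
  stopifnot(inherits(rule, "threshold_rule"))
  s_pres <- extract_at_points(suitability, presences$records$x,
                              presences$records$y)
  s_pres <- s_pres[is.finite(s_pres)]
  if (length(s_pres) == 0) stop("no presence falls on an unmasked cell")
  if (rule$rule_id == "fixed_value") return(rule$parameter)
  if (rule$rule_id == "training_presence_percentile") {
    sorted <- sort(s_pres)
    rank <- max(1L, ceiling(rule$parameter / 100 * length(sorted)))
    return(sorted[min(rank, length(sorted))])
  }
  s_bg <- extract_at_points(suitability, background$records$x,
                            background$records$y)
  s_bg <- s_bg[is.finite(s_bg)]
  cand <- sort(unique(c(s_pres, s_bg)))
  if (length(cand) == 1) {
    warning("degenerate suitability distribution; falling back to threshold 0.5")
    return(0.5)
  }
  sp <- sort(s_pres); sb <- sort(s_bg)
  # sens(t) = P(presence >= t), spec(t) = P(background < t)
  sens <- (length(sp) - findInterval(cand, sp, left.open = TRUE)) / length(sp)
  spc <- findInterval(cand, sb, left.open = TRUE) / length(sb)
  score <- sens + spc
  cand[which(score >= max(score) - 1e-12)[1]]
}

#' Threshold a suitability map to binary presence/absence
#'
#' Cells with suitability greater than or equal to the threshold become
#' 1 (presence), others 0; masked cells stay masked.
#'
#' @param suitability a suitability `grid_layer`.
#' @param threshold a number in `(0, 1)`.
#' @return A binary `grid_layer`.
#' @export
threshold_map <- function(suitability, threshold) {
  stopifnot(inherits(suitability, "grid_layer"),
            is.finite(threshold), threshold > 0, threshold < 1)
  grid_layer(suitability$geometry,
             ifelse(suitability$values >= threshold, 1, 0))
}
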