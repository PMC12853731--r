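# Partial dependence: 1D curves, binary/level handling, 2D surfaces, bands.

pdp_transform <- function(p, scale) {
  if (scale == "log-odds") stats::qlogis(clip_prob(p)) else p
}

new_pdp_curve <- function(feature, grid, values, scale, n_background,
                          band_low = NULL, band_high = NULL, difference = NULL) {
  structure(
    list(feature = feature, grid = grid, values = values, scale = scale,
         band_low = band_low, band_high = band_high,
         n_background = n_background, difference = difference),
    class = "pdp_curve"
  )
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat(sprintf("<pdp_curve> %s: %d grid points on %s scale (background n = %d)\n",
              x$feature, length(x$grid), x$scale, x$n_background))
  invisible(x)
}

# population-average prediction with `feature` clamped to each grid value;
# one batched prediction call per chunk of grid points
pdp_average <- function(model, background, feature, grid, scale,
                        chunk_rows = 200000) {
  n <- nrow(background)
  per_chunk <- max(1L, floor(chunk_rows / n))
  vals <- numeric(length(grid))
  done <- 0L
  while (done < length(grid)) {
    take <- seq(done + 1L, min(done + per_chunk, length(grid)))
    stacked <- background[rep(seq_len(n), length(take)), , drop = FALSE]
    stacked[[feature]] <- rep(grid[take], each = n)
    tr <- pdp_transform(predict_risk(model, stacked), scale)
    vals[take] <- colMeans(matrix(tr, nrow = n))
    done <- done + length(take)
  }
  vals
}

#' One-dimensional partial dependence curve
#'
#' Grid of equally spaced points spanning the feature's 5th-95th percentile in
#' the background table (falling back to the full observed range when heavy
#' imputation collapses the percentile window onto a single value); the value
#' at each grid point is the mean over background rows of the model's
#' prediction with the feature clamped to that point. On the log-odds scale, predictions are logit-transformed (after
#' clipping) *before* averaging.
#'
#' @param model a model exposing [predict_risk()].
#' @param background complete background data.frame.
#' @param feature continuous feature name.
#' @param grid_size number of grid points (default 50).
#' @param scale `"probability"` or `"log-odds"`.
#' @param lower,upper percentile window (defaults 0.05, 0.95).
#' @return a `pdp_curve`.
#' @export
pdp_1d <- function(model, background, feature, grid_size = 50,
                   scale = c("probability", "log-odds"),
                   lower = 0.05, upper = 0.95) {
  scale <- match.arg(scale)
  background <- as.data.frame(background)
  x <- background[[feature]]
  if (is.null(x)) pa_abort(paste("unknown feature:", feature), "unknown_feature")
  qs <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
  if (qs[1] == qs[2]) {
    # heavily imputed features can concentrate >90% of their mass on one
    # value, collapsing the percentile window; fall back to the full range
    qs <- range(x)
    if (qs[1] == qs[2]) {
      pa_abort(paste("degenerate grid: feature", feature, "is constant"),
               "degenerate_grid")
    }
  }
  grid <- seq(qs[1], qs[2], length.out = grid_size)
  vals <- pdp_average(model, background, feature, grid, scale)
  new_pdp_curve(feature, grid, vals, scale, nrow(background))
}

# partial dependence evaluated at an explicit, non-interpolated level set
pdp_levels <- function(model, background, feature, levels, scale = "log-odds") {
  background <- as.data.frame(background)
  vals <- pdp_average(model, background, feature, levels, scale)
  new_pdp_curve(feature, levels, vals, scale, nrow(background))
}

#' Partial dependence for a binary feature (no interpolation)
#'
#' Evaluates the population-average prediction at the two declared levels only
#' and reports the level-1 minus level-0 difference (in log-odds by default),
#' the scale on which binary risk differences are reported.
#'
#' @inheritParams pdp_1d
#' @param feature binary feature name.
#' @param levels the two levels to clamp to (default `c(0, 1)`).
#' @return a `pdp_curve` with two grid points and a `difference` field.
#' @export
pdp_binary <- function(model, background, feature,
                       scale = c("log-odds", "probability"), levels = c(0, 1)) {
  scale <- match.arg(scale)
  background <- as.data.frame(background)
  x <- background[[feature]]
  if (is.null(x)) pa_abort(paste("unknown feature:", feature), "unknown_feature")
  if (length(levels) != 2L) pa_abort("levels must have length 2", "non_binary")
  if (length(unique(x)) > 3L) {
    pa_abort(paste("feature", feature, "does not look binary"), "non_binary")
  }
  cur <- pdp_levels(model, background, feature, levels, scale)
  cur$difference <- cur$values[2] - cur$values[1]
  cur
}

#' Two-dimensional partial dependence surface
#'
#' Subsamples the background without replacement (seeded), clamps both
#' features over the grid product, and averages as in [pdp_1d()]. Features
#' with at most 10 distinct background values (binary/ordinal) use their
#' observed levels as the grid — never interpolated; continuous features use
#' an equally spaced grid over their 5th-95th percentile window.
#'
#' @inheritParams pdp_1d
#' @param pair character vector of two feature names.
#' @param grid_size grid points per continuous feature (default 20).
#' @param n_subsample background rows used (default 5000); must not exceed the
#'   background size.
#' @param seed integer seed for the subsample.
#' @return an object of class `pdp_surface`: `feature_a`, `feature_b`,
#'   `grid_a`, `grid_b`, `values` (matrix, rows = grid_a), `scale`,
#'   `n_subsample`.
#' @export
pdp_2d <- function(model, background, pair, grid_size = 20, n_subsample = 5000,
                   seed = 1, scale = c("probability", "log-odds"),
                   lower = 0.05, upper = 0.95) {
  scale <- match.arg(scale)
  background <- as.data.frame(background)
  stopifnot(length(pair) == 2L)
  if (nrow(background) < n_subsample) {
    pa_abort("background has fewer rows than n_subsample", "invalid_input")
  }
  set.seed(seed)
  bg <- background[sort(sample.int(nrow(background), n_subsample)), , drop = FALSE]
  grid_for <- function(f) {
    x <- bg[[f]]
    if (is.null(x)) pa_abort(paste("unknown feature:", f), "unknown_feature")
    ux <- sort(unique(x))
    if (length(ux) <= 10L) return(ux)
    qs <- stats::quantile(x, c(lower, upper), names = FALSE, type = 7)
    if (qs[1] == qs[2]) pa_abort(paste("degenerate grid for", f), "degenerate_grid")
    seq(qs[1], qs[2], length.out = grid_size)
  }
  ga <- grid_for(pair[1]); gb <- grid_for(pair[2])
  vals <- matrix(NA_real_, length(ga), length(gb))
  n <- nrow(bg)
  for (jb in seq_along(gb)) {
    tmp <- bg
    tmp[[pair[2]]] <- gb[jb]
    vals[, jb] <- pdp_average(model, tmp, pair[1], ga, scale)
  }
  structure(
    list(feature_a = pair[1], feature_b = pair[2], grid_a = ga, grid_b = gb,
         values = vals, scale = scale, n_subsample = n_subsample),
    class = "pdp_surface"
  )
}

#' @export
print.pdp_surface <- function(x, ...) {
  cat(sprintf("<pdp_surface> %s x %s: %d x %d grid on %s scale (n_subsample = %d)\n",
              x$feature_a, x$feature_b, length(x$grid_a), length(x$grid_b),
              x$scale, x$n_subsample))
  invisible(x)
}

#' Bootstrap confidence band for a 1D partial dependence curve
#'
#' Draws `B` resamples of size `m` with replacement from the background,
#' recomputes the curve on the *fixed* full-background grid for each resample,
#' and reports per-grid-point percentile intervals at the stated level around
#' the full-background curve.
#'
#' @inheritParams pdp_1d
#' @param B number of resamples (default 50).
#' @param m resample size (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return a `pdp_curve` with `band_low`/`band_high` filled in.
#' @export
pdp_bootstrap_band <- function(model, background, feature, B = 50, m = 2000,
                               seed = 1, level = 0.95, grid_size = 50,
                               scale = c("probability", "log-odds"),
                               lower = 0.05, upper = 0.95) {
  scale <- match.arg(scale)
  if (B < 2) pa_abort("B must be at least 2", "invalid_input")
  background <- as.data.frame(background)
  full <- pdp_1d(model, background, feature, grid_size, scale, lower, upper)
  set.seed(seed)
  n <- nrow(background)
  boot_vals <- matrix(NA_real_, B, length(full$grid))
  for (b in seq_len(B)) {
    idx <- sample.int(n, m, replace = TRUE)
    boot_vals[b, ] <- pdp_average(model, background[idx, , drop = FALSE],
                                  feature, full$grid, scale)
  }
  alpha <- (1 - level) / 2
  full$band_low <- apply(boot_vals, 2, stats::quantile, probs = alpha, type = 7)
  full$band_high <- apply(boot_vals, 2, stats::quantile, probs = 1 - alpha, type = 7)
  full
}

#' Overall trend direction of a partial dependence curve
#'
#' The least-squares slope of curve values against the grid; the sign is
#' reported as 0 (flat) when the absolute total rise — slope times grid span —
#' is below `1e-4` on the curve's scale.
#'
#' @param curve a `pdp_curve` with at least 2 points.
#' @param dead_zone flat-classification threshold on the total rise.
#' @return an object of class `direction_result`: `feature`, `slope_sign`,
#'   `slope_value`, `method`.
#' @export
trend_direction <- function(curve, dead_zone = 1e-4) {
  stopifnot(length(curve$grid) >= 2L)
  g <- curve$grid - mean(curve$grid)
  slope <- sum(g * (curve$values - mean(curve$values))) / sum(g^2)
  rise <- slope * (max(curve$grid) - min(curve$grid))
  sgn <- if (abs(rise) < dead_zone) 0L else as.integer(sign(slope))
  structure(
    list(feature = curve$feature, slope_sign = sgn, slope_value = slope,
         method = "ols_slope"),
    class = "direction_result"
  )
}
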