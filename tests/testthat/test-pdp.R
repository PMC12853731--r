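test_that("1D partial dependence matches analytic oracles", {
  set.seed(1)
  bg <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
  # risk depends on x1 only: marginalisation is trivial and the curve is s(g)
  m <- linear_oracle(c(x1 = 1, x2 = 0))
  cur <- pdp_1d(m, bg, "x1", grid_size = 21)
  expect_equal(cur$values, plogis(cur$grid), tolerance = 1e-2)
  # grid spans the central 90% of the background
  qs <- quantile(bg$x1, c(0.05, 0.95), names = FALSE)
  expect_equal(range(cur$grid), qs)
  expect_equal(length(cur$grid), 21)

  # constant model: flat curve at the constant
  mc <- linear_oracle(c(x1 = 0, x2 = 0), intercept = qlogis(0.3))
  flat <- pdp_1d(mc, bg, "x1", grid_size = 5)
  expect_equal(flat$values, rep(0.3, 5), tolerance = 1e-12)

  expect_error(pdp_1d(m, transform(bg, x1 = 1), "x1"), class = "degenerate_grid")
  expect_error(pdp_1d(m, bg, "nope"), class = "unknown_feature")
})

test_that("1D and 2D partial dependence equal brute-force clamped means on small backgrounds", {
  fx <- cached_small_fit()
  bg <- fx$data[1:5, ]
  cur <- pdp_1d(fx$model, bg, "x1", grid_size = 3)
  expect_equal(cur$values, brute_pdp_1d(fx$model, bg, "x1", cur$grid),
               tolerance = 1e-10)
  curlo <- pdp_1d(fx$model, bg, "x1", grid_size = 3, scale = "log-odds")
  expect_equal(curlo$values, brute_pdp_1d(fx$model, bg, "x1", curlo$grid, "log-odds"),
               tolerance = 1e-10)

  bg50 <- fx$data[1:50, ]
  sur <- pdp_2d(fx$model, bg50, c("x1", "x2"), grid_size = 4, n_subsample = 50,
                seed = 1)
  expect_equal(sur$values,
               brute_pdp_2d(fx$model, bg50, c("x1", "x2"), sur$grid_a, sur$grid_b),
               tolerance = 1e-10)
})

test_that("binary partial dependence never interpolates and reports the log-odds gap", {
  set.seed(3)
  bg <- data.frame(xb = rbinom(300, 1, 0.4), xc = rnorm(300))
  # planted binary effect of +0.3 log-odds
  m <- linear_oracle(c(xb = 0.3, xc = 0.5))
  cur <- pdp_binary(m, bg, "xb")
  expect_equal(cur$grid, c(0, 1))
  expect_equal(cur$difference, 0.3, tolerance = 1e-9)
  # a model ignoring the feature shows no gap
  m0 <- linear_oracle(c(xb = 0, xc = 0.5))
  expect_equal(pdp_binary(m0, bg, "xb")$difference, 0, tolerance = 1e-12)
  expect_error(pdp_binary(m, bg, "xc"), class = "non_binary")
})

test_that("2D surfaces are additive for additive models and flat along unused axes", {
  set.seed(5)
  bg <- data.frame(a = rnorm(500), b = rnorm(500))
  m <- linear_oracle(c(a = 0.8, b = -0.6))
  sur <- pdp_2d(m, bg, c("a", "b"), grid_size = 6, n_subsample = 400, seed = 2,
                scale = "log-odds")
  ca <- pdp_1d(m, bg, "a", grid_size = 6, scale = "log-odds")
  # additive log-odds: surface = row effect + column effect + constant
  recon <- outer(0.8 * sur$grid_a, -0.6 * sur$grid_b, `+`)
  shift <- mean(sur$values - recon)
  expect_lt(max(abs(sur$values - recon - shift)), 0.02)

  m1 <- linear_oracle(c(a = 0.8, b = 0))
  sur1 <- pdp_2d(m1, bg, c("a", "b"), grid_size = 5, n_subsample = 400, seed = 2)
  expect_lt(max(abs(sur1$values - sur1$values[, 1])), 0.01)

  # discrete features keep their observed levels as the grid
  bg$lvl <- sample(0:2, 500, replace = TRUE)
  m2 <- linear_oracle(c(a = 0.5, lvl = 0.2))
  sur2 <- pdp_2d(m2, bg, c("a", "lvl"), grid_size = 7, n_subsample = 400, seed = 3)
  expect_equal(sur2$grid_b, 0:2)

  expect_error(pdp_2d(m, bg, c("a", "b"), n_subsample = 10000), class = "invalid_input")
})

test_that("bootstrap bands are seeded, bracket the point curve, and collapse for constant models", {
  bg <- data.frame(x1 = rnorm(500), x2 = rnorm(500))
  mc <- linear_oracle(c(x1 = 0, x2 = 0), intercept = 0.4)
  band0 <- pdp_bootstrap_band(mc, bg, "x1", B = 10, m = 100, seed = 1, grid_size = 5)
  expect_equal(band0$band_low, band0$values, tolerance = 1e-12)
  expect_equal(band0$band_high, band0$values, tolerance = 1e-12)

  fx <- cached_small_fit()
  for (s in 1:5) {
    band <- pdp_bootstrap_band(fx$model, fx$data, "x1", B = 50, m = 400,
                               seed = s, grid_size = 10)
    coverage <- mean(band$band_low <= band$values & band$values <= band$band_high)
    expect_gte(coverage, 0.9)
  }
  b1 <- pdp_bootstrap_band(fx$model, fx$data, "x1", B = 10, m = 200, seed = 3,
                           grid_size = 6)
  b2 <- pdp_bootstrap_band(fx$model, fx$data, "x1", B = 10, m = 200, seed = 3,
                           grid_size = 6)
  expect_identical(b1, b2)
  expect_error(pdp_bootstrap_band(fx$model, fx$data, "x1", B = 1), class = "invalid_input")
})

test_that("trend direction reads the least-squares slope with a flat dead-zone", {
  up <- structure(list(feature = "f", grid = 1:5, values = c(1, 2, 3, 4, 5) / 10,
                       scale = "probability"), class = "pdp_curve")
  expect_identical(trend_direction(up)$slope_sign, 1L)
  down <- up; down$values <- rev(up$values)
  expect_identical(trend_direction(down)$slope_sign, -1L)
  flat <- up; flat$values <- rep(0.3, 5) + c(0, 1e-6, -1e-6, 0, 0)
  expect_identical(trend_direction(flat)$slope_sign, 0L)

  # protective oracle: risk = s(-x) gives a negative trend
  bg <- data.frame(x = rnorm(300), z = rnorm(300))
  m <- linear_oracle(c(x = -1, z = 0))
  expect_identical(trend_direction(pdp_1d(m, bg, "x", grid_size = 15))$slope_sign, -1L)
})

test_that("probability and log-odds curves agree in direction away from saturation", {
  set.seed(6)
  bg <- data.frame(x = rnorm(300), z = rnorm(300))
  for (w in c(-0.8, -0.2, 0.3, 1.1)) {
    m <- linear_oracle(c(x = w, z = 0.3))
    d_p <- trend_direction(pdp_1d(m, bg, "x", grid_size = 12, scale = "probability"))
    d_l <- trend_direction(pdp_1d(m, bg, "x", grid_size = 12, scale = "log-odds"))
    expect_identical(d_p$slope_sign, d_l$slope_sign)
    expect_identical(d_p$slope_sign, as.integer(sign(w)))
  }
  fx <- cached_small_fit()
  d_p <- trend_direction(pdp_1d(fx$model, fx$data, "x1", grid_size = 12))
  d_l <- trend_direction(pdp_1d(fx$model, fx$data, "x1", grid_size = 12,
                                scale = "log-odds"))
  expect_identical(d_p$slope_sign, d_l$slope_sign)
})
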