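test_that("interaction columns are exact products of stored z-scores", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  ispec <- make_interaction_spec(d, 1:3, data.frame(a = "a", b = "b"))
  out <- build_interaction_features(d, ispec)
  expect_equal(ncol(out), 3)
  # hand-computed: z(a) = (-1, 0, 1); z(b) = (x - 70/3) / 15.27525...
  expect_equal(out$a_x_b, c(0.8728716, 0, 1.0910895), tolerance = 1e-6)
  # a at its training mean zeroes the product regardless of b
  expect_equal(out$a_x_b[2], 0)

  # self-pair gives z squared
  ispec2 <- make_interaction_spec(d, 1:3, data.frame(a = "a", b = "a"))
  out2 <- build_interaction_features(d, ispec2)
  expect_equal(out2$a_x_a, c(1, 0, 1))

  # stats come from training rows only, so columns are reproducible elsewhere
  ispec3 <- make_interaction_spec(d, 1:2, data.frame(a = "a", b = "b"))
  za <- (3 - 1.5) / sd(c(1, 2)); zb <- (40 - 15) / sd(c(10, 20))
  expect_equal(build_interaction_features(d, ispec3)$a_x_b[3], za * zb)

  expect_error(make_interaction_spec(d, 1:3, data.frame(a = c("a", "b"), b = c("b", "a"))),
               class = "invalid_spec")  # duplicate unordered pair
  expect_error(make_interaction_spec(d, 1:3, data.frame(a = "a", b = "zz")),
               class = "unknown_feature")
  dd <- data.frame(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(make_interaction_spec(dd, 1:3, data.frame(a = "a", b = "b")),
               class = "degenerate_feature")
  expect_error(build_interaction_features(data.frame(a = c(1, NA), b = c(1, 2)), ispec),
               class = "invalid_input")
})

test_that("default interaction pairs: 24 unique pairs over declared features", {
  pairs <- default_interaction_pairs()
  expect_equal(nrow(pairs), 24)
  key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(c(pairs$a, pairs$b) %in% names(default_nsqip_specs())))
  # the five dominant registry pairs are included
  expect_true(all(c("age asa_class", "asa_class operative_time",
                    "age operative_time", "asa_class preop_hematocrit",
                    "diabetes preop_hematocrit") %in% key))
})

test_that("AUC equals the Mann-Whitney pair count with half-credit ties", {
  expect_equal(auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), class = "undefined_auc")

  # invariance under strictly increasing transforms
  set.seed(4)
  y <- rbinom(200, 1, 0.3); s <- runif(200)
  expect_equal(auc(y, s), auc(y, qlogis(s)))
  expect_equal(auc(y, s), auc(y, 100 * s + 3))

  # cross-check against an independent implementation
  expect_equal(auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("bootstrap AUC interval brackets the point estimate deterministically", {
  set.seed(8)
  y <- rbinom(300, 1, 0.2); s <- plogis(rnorm(300) + y)
  ci <- auc_ci(y, s, B = 200, seed = 2)
  point <- attr(ci, "point")
  expect_lt(ci["lower"], point)
  expect_gt(ci["upper"], point)
  expect_identical(ci, auc_ci(y, s, B = 200, seed = 2))
})

test_that("tuning selects from the declared grid and refits deterministically", {
  set.seed(3)
  n <- 2000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(d$x1 > 0)
  one_point <- list(num_trees = 80, max_depth = 8, min_split = 10, min_leaf = 5)
  m <- tune_and_fit(d, y, ranges = one_point, seed = 6)
  expect_equal(m$hyperparameters, one_point)
  expect_equal(m$training_meta$grid_size, 1)
  # separable toy: near-perfect training discrimination
  expect_gt(auc(y, predict_risk(m, d)), 0.95)

  # identical seed, identical selection and predictions
  ranges2 <- list(num_trees = 50, max_depth = c(4, 8), min_split = 10, min_leaf = 5)
  m1 <- tune_and_fit(d, y, ranges = ranges2, grid_points = 2, cv_folds = 3,
                     subsample_n = 600, seed = 11)
  m2 <- tune_and_fit(d, y, ranges = ranges2, grid_points = 2, cv_folds = 3,
                     subsample_n = 600, seed = 11)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(predict_risk(m1, d[1:50, ]), predict_risk(m2, d[1:50, ]))
})

test_that("predict_risk enforces the feature contract and clips probabilities", {
  fx <- cached_small_fit()
  p <- predict_risk(fx$model, fx$data)
  expect_length(p, nrow(fx$data))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
  # extra columns ignored; missing features are an error
  extra <- cbind(fx$data, junk = 1)
  expect_equal(predict_risk(fx$model, extra), p)
  expect_error(predict_risk(fx$model, fx$data[, 1:2]), class = "unknown_feature")
})

test_that("interaction-model wrapper rebuilds product columns before predicting", {
  set.seed(12)
  n <- 500
  d <- data.frame(u = rnorm(n), v = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + d$u * d$v))
  ispec <- make_interaction_spec(d, seq_len(n), data.frame(a = "u", b = "v"))
  dw <- build_interaction_features(d, ispec)
  fit <- tune_and_fit(dw, y, ranges = list(num_trees = 50, max_depth = 6,
                                           min_split = 10, min_leaf = 5), seed = 2)
  wrapped <- interaction_risk_model(fit, ispec)
  expect_equal(predict_risk(wrapped, d), predict_risk(fit, dw))
  # clamping u through the wrapper moves u_x_v too: the wrapped PDP of u is
  # not flat even though u alone carries no main effect
  cur <- pdp_2d(wrapped, d, c("u", "v"), grid_size = 5, n_subsample = 200, seed = 1)
  expect_gt(diff(range(cur$values)), 0.01)
})
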