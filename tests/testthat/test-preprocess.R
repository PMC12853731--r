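toy_specs <- function() {
  list(
    age = feature_spec("age", "continuous", mean = 67, sd = 10),
    preop_hematocrit = feature_spec("preop_hematocrit", "continuous", mean = 41.4,
                                    sd = 4.1, physiologic_range = c(15, 60)),
    bmi = feature_spec("bmi", "continuous", mean = 31.8, sd = 6.5,
                       physiologic_range = c(10, 80)),
    elective = feature_spec("elective", "binary", prevalence = 0.979,
                            sentinel_codes = -1)
  )
}

test_that("sentinel recoding maps tokens and codes, leaves the rest untouched", {
  specs <- toy_specs()
  d <- data.frame(age = c("70.5", "90+", "55"),
                  preop_hematocrit = c(41, -99, 38),
                  bmi = c(30, 31, 32),
                  elective = c(1, 0, -1))
  co <- toy_cohort(d, specs)
  out <- recode_sentinels(co)
  expect_equal(out$data$age, c(70.5, 90, 55))
  expect_false(out$missing_mask[2, "age"])       # "90+" is a value, not missing
  expect_true(is.na(out$data$preop_hematocrit[2]))
  expect_true(out$missing_mask[2, "preop_hematocrit"])
  expect_true(is.na(out$data$elective[3]))
  expect_equal(out$data$bmi, d$bmi)              # untouched column

  # a cohort with no sentinels or tokens recodes to itself
  clean <- toy_cohort(data.frame(age = c(60, 61), preop_hematocrit = c(40, 41),
                                 bmi = c(30, 31), elective = c(1, 0)), specs)
  expect_identical(recode_sentinels(clean), clean)

  # an unparseable token is reported with its location
  bad <- toy_cohort(data.frame(age = c("70", "oops", "80"),
                               preop_hematocrit = c(41, 42, 43),
                               bmi = c(30, 31, 32), elective = c(1, 1, 0)), specs)
  err <- tryCatch(recode_sentinels(bad), error = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "age")
})

test_that("physiologic filters remove planted violations, keep bounds and missing rows", {
  specs <- toy_specs()
  # 10 rows, exactly 2 violations: hematocrit 12 (row 2) and BMI 9 (row 5);
  # row 7 sits exactly at the BMI bound and row 9 is entirely missing
  d <- data.frame(
    age = c(60, 61, 62, 63, 64, 65, 66, 67, NA, 69),
    preop_hematocrit = c(40, 12, 41, 42, 43, 44, 45, 46, NA, 60),
    bmi = c(30, 31, 32, 33, 9, 35, 10, 37, NA, 80),
    elective = c(1, 1, 0, 1, 1, 0, 1, 1, NA, 1)
  )
  co <- toy_cohort(d, specs)
  res <- apply_physiologic_filters(co)
  expect_equal(sum(res$report$n_removed), 2)
  expect_equal(res$report$n_removed[res$report$rule == "preop_hematocrit_range"], 1)
  expect_equal(res$report$n_removed[res$report$rule == "bmi_range"], 1)
  expect_equal(nrow(res$cohort$data), 8)
  expect_true(10 %in% res$cohort$data$bmi)       # value at the bound retained
  expect_true(60 %in% res$cohort$data$preop_hematocrit)
  expect_true(anyNA(res$cohort$data$age))        # all-missing row retained

  # idempotence: a second pass removes nothing
  res2 <- apply_physiologic_filters(res$cohort)
  expect_equal(sum(res2$report$n_removed), 0)
  expect_identical(res2$cohort$data, res$cohort$data)
})

test_that("median imputation fills from fitting rows only and never edits observed cells", {
  specs <- toy_specs()
  d <- data.frame(age = c(1, 2, 3, NA, 100, 200),
                  preop_hematocrit = c(40, 41, 42, 43, NA, 45),
                  bmi = rep(30, 6),
                  elective = c(1, 0, 1, NA, 1, 0))
  co <- toy_cohort(d, specs)
  out <- impute_median(co, fit_ids = 1:4)
  expect_equal(out$data$age[4], 2)               # median of {1,2,3} over fit rows
  expect_equal(out$data$preop_hematocrit[5], 41.5) # train median, not the test one
  expect_equal(out$data$elective[4], 2)          # explicit missing category
  observed <- !co$missing_mask
  expect_equal(as.matrix(out$data)[observed], as.matrix(co$data)[observed])

  # no missing cells: identity
  clean <- toy_cohort(data.frame(age = 1:3, preop_hematocrit = c(40, 41, 42),
                                 bmi = c(30, 31, 32), elective = c(1, 0, 1)), specs)
  expect_identical(impute_median(clean, 1:3), clean)

  # entirely-missing feature over fitting rows is a failure signal
  allmiss <- toy_cohort(data.frame(age = c(NA_real_, NA_real_, 3),
                                   preop_hematocrit = c(40, 41, 42),
                                   bmi = c(30, 31, 32), elective = c(1, 0, 1)), specs)
  expect_error(impute_median(allmiss, 1:2), class = "imputation_failure")
  expect_error(impute_median(allmiss, integer(0)), class = "invalid_input")
})

test_that("chained-equations imputation is complete, deterministic, and identity without missingness", {
  specs2 <- list(x1 = feature_spec("x1", "continuous", mean = 0, sd = 1),
                 x2 = feature_spec("x2", "continuous", mean = 0, sd = 2.5))
  set.seed(5)
  n <- 400
  x1 <- rnorm(n); x2 <- 2 * x1 + rnorm(n)
  x2[sample(n, 120)] <- NA
  co <- toy_cohort(data.frame(x1 = x1, x2 = x2), specs2,
                   outcome = rbinom(n, 1, 0.2))
  out <- impute_chained(co, fit_ids = seq_len(n), m = 5, seed = 9, sweeps = 5)
  expect_length(out, 5)
  for (k in 1:5) expect_false(anyNA(out[[k]]$data))
  # observed cells never modified
  obs <- !is.na(x2)
  expect_equal(out[[1]]$data$x2[obs], x2[obs])
  # identical seed, identical output
  out2 <- impute_chained(co, fit_ids = seq_len(n), m = 5, seed = 9, sweeps = 5)
  expect_identical(out[[3]]$data, out2[[3]]$data)
  expect_error(impute_chained(co, seq_len(n), m = 1), class = "invalid_input")

  # no missing cells: m identical copies of the input
  clean <- toy_cohort(data.frame(x1 = x1, x2 = 2 * x1), specs2)
  copies <- impute_chained(clean, seq_len(n), m = 3, seed = 1)
  expect_length(copies, 3)
  expect_identical(copies[[2]], clean)
})

test_that("chained imputation preserves a planted linear relation", {
  specs2 <- list(x1 = feature_spec("x1", "continuous", mean = 0, sd = 1),
                 x2 = feature_spec("x2", "continuous", mean = 0, sd = 2.5))
  slopes <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 5000
    x1 <- rnorm(n)
    x2 <- 2 * x1 + rnorm(n)
    x2[sample(n, round(0.3 * n))] <- NA
    co <- toy_cohort(data.frame(x1 = x1, x2 = x2), specs2,
                     outcome = rbinom(n, 1, 0.1))
    imp <- impute_chained(co, fit_ids = seq_len(n), m = 2, seed = s, sweeps = 5)
    coef(lm(imp[[1]]$data$x2 ~ imp[[1]]$data$x1))[2]
  }, numeric(1))
  expect_true(all(abs(slopes - 2) < 0.3))
})

test_that("stratified split preserves the outcome rate and partitions exactly", {
  y <- c(rep(1L, 10), rep(0L, 90))
  sp <- stratified_split(y, 0.8, seed = 1)
  expect_equal(sum(y[sp$train_ids]), 8)
  expect_equal(sum(y[sp$test_ids]), 2)
  expect_equal(length(sp$train_ids) + length(sp$test_ids), 100)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # deterministic
  sp2 <- stratified_split(y, 0.8, seed = 1)
  expect_identical(sp, sp2)
  # degenerate class
  expect_error(stratified_split(rep(0L, 10)), class = "split_failure")
  expect_error(stratified_split(c(rep(0L, 9), 1L)), class = "split_failure")
  # per-class counts within one patient of the target fraction
  set.seed(2)
  y2 <- rbinom(10000, 1, 0.067)
  sp3 <- stratified_split(y2, 0.8, seed = 3)
  for (cl in 0:1) {
    expect_lte(abs(sum(y2[sp3$train_ids] == cl) - 0.8 * sum(y2 == cl)), 1)
  }
})
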