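# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# default planted-effect ground truth, calibrated once
cached_default_gt <- function() {
  cache_get("default_gt", function() {
    specs <- default_nsqip_specs()
    gt <- default_ground_truth(specs)
    gt$intercept <- calibrate_intercept(gt, specs, n_probe = 100000, seed = 1000)
    gt
  })
}

# monotone strong-effect ground truth for concordance recovery, calibrated once
cached_recovery_gt <- function() {
  cache_get("recovery_gt", function() {
    specs <- default_nsqip_specs()
    gt <- ground_truth_recovery(specs)
    gt$intercept <- calibrate_intercept(gt, specs, n_probe = 100000, seed = 1000)
    gt
  })
}

# a small fitted Random-Forest risk model with its data, for oracle-equality
# and band tests
cached_small_fit <- function() {
  cache_get("small_fit", function() {
    set.seed(42)
    n <- 600
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- rbinom(n, 1, plogis(d$x1 - d$x2))
    model <- tune_and_fit(d, y,
                          ranges = list(num_trees = 50, max_depth = 6,
                                        min_split = 10, min_leaf = 5),
                          seed = 7)
    list(model = model, data = d, y = y)
  })
}

# hand-buildable cohort around explicit values (mask derived from NAs unless given)
toy_cohort <- function(data, specs, outcome = NULL, mask = NULL) {
  if (is.null(outcome)) {
    outcome <- rep(0L, nrow(data))
    outcome[1] <- 1L  # keep both classes representable where needed
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(data), ncol(data),
                   dimnames = list(NULL, names(data)))
    for (nm in names(data)) {
      if (is.numeric(data[[nm]])) mask[, nm] <- is.na(data[[nm]])
    }
  }
  cohort_table(data, outcome, mask, specs)
}
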