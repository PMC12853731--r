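# Model layer: interaction features, tree-ensemble fitting, AUC.

#' Build an interaction specification from training rows
#'
#' Records the unordered feature pairs and the training-row means and SDs used
#' to standardise them, so interaction columns are exactly reproducible later
#' (on test rows, bootstrap resamples, or external cohorts) from the stored
#' statistics alone.
#'
#' @param data complete numeric data.frame.
#' @param train_ids rows the standardisation statistics are computed from.
#' @param pairs data.frame with columns `a`, `b` (no duplicate unordered
#'   pairs), e.g. [default_interaction_pairs()].
#' @return an object of class `interaction_spec`.
#' @export
make_interaction_spec <- function(data, train_ids, pairs = default_interaction_pairs()) {
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
  key <- apply(cbind(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b)), 1, paste,
               collapse = "|")
  if (anyDuplicated(key)) pa_abort("duplicate unordered interaction pair", "invalid_spec")
  feats <- unique(c(pairs$a, pairs$b))
  unknown <- setdiff(feats, names(data))
  if (length(unknown)) {
    pa_abort(paste("unknown feature(s) in pairs:", paste(unknown, collapse = ", ")),
             "unknown_feature")
  }
  stats <- data.frame(
    feature = feats,
    mean = vapply(feats, function(f) mean(data[[f]][train_ids]), numeric(1)),
    sd = vapply(feats, function(f) stats::sd(data[[f]][train_ids]), numeric(1)),
    stringsAsFactors = FALSE
  )
  zero <- stats$feature[stats$sd == 0 | is.na(stats$sd)]
  if (length(zero)) {
    pa_abort(paste("zero training SD for:", paste(zero, collapse = ", ")),
             "degenerate_feature")
  }
  structure(list(pairs = pairs[c("a", "b")], stats = stats),
            class = "interaction_spec")
}

#' Append product-of-standardised-features interaction columns
#'
#' For each pair `(a, b)` appends a column named `a_x_b` equal to
#' `z(a) * z(b)`, with `z` standardised by the training statistics stored in
#' the interaction spec. Original columns are unchanged.
#'
#' @param data complete numeric data.frame (no missing cells).
#' @param ispec an [make_interaction_spec()] result.
#' @return `data` with one extra column per pair.
#' @export
build_interaction_features <- function(data, ispec) {
  if (anyNA(data)) pa_abort("data must be complete (imputed) first", "invalid_input")
  st <- ispec$stats
  z <- function(f) (data[[f]] - st$mean[st$feature == f]) / st$sd[st$feature == f]
  for (i in seq_len(nrow(ispec$pairs))) {
    a <- ispec$pairs$a[i]; b <- ispec$pairs$b[i]
    data[[paste0(a, "_x_", b)]] <- z(a) * z(b)
  }
  data
}

#' Default interaction pair list (24 pairs)
#'
#' The six clinically named pairs (BMI x age, diabetes x smoking, age x ASA,
#' functional status x age, BMI x diabetes, smoking x COPD), the five pairs
#' found dominant in registry analyses (age x ASA, operative time x ASA,
#' operative time x age, hematocrit x ASA, hematocrit x diabetes — one of
#' which duplicates age x ASA), and 14 declared filler pairs to reach 24.
#'
#' @return data.frame with columns `a`, `b`.
#' @export
default_interaction_pairs <- function() {
  data.frame(
    a = c("bmi", "diabetes", "age", "functional_dependent", "bmi", "smoking",
          "operative_time", "operative_time", "preop_hematocrit", "preop_hematocrit",
          "sex_female", "preop_albumin", "preop_creatinine", "hemoglobin_a1c",
          "chf", "copd", "hypertension", "steroid_use", "bleeding_disorder",
          "preop_albumin", "preop_creatinine", "sex_female", "hypertension",
          "elective"),
    b = c("age", "smoking", "asa_class", "age", "diabetes", "copd",
          "asa_class", "age", "asa_class", "diabetes",
          "age", "age", "asa_class", "diabetes",
          "asa_class", "operative_time", "age", "asa_class", "operative_time",
          "asa_class", "age", "operative_time", "bmi",
          "operative_time"),
    stringsAsFactors = FALSE
  )
}

#' Hyperparameter search ranges for the tree ensemble
#'
#' Number of trees 100-300, maximum depth 5-15, minimum node size to split
#' 5-15, minimum terminal-node (leaf) size 2-8.
#'
#' @return a named list of length-2 ranges (or length-1 for a fixed value).
#' @export
hyper_ranges <- function() {
  list(num_trees = c(100, 300), max_depth = c(5, 15),
       min_split = c(5, 15), min_leaf = c(2, 8))
}

hyper_grid <- function(ranges, grid_points = 3) {
  vals <- lapply(ranges, function(r) {
    if (length(r) == 1) return(r)
    unique(round(seq(r[1], r[2], length.out = grid_points)))
  })
  expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
}

fit_ranger <- function(x, y, hp, seed, num_threads = 1) {
  ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
    num.trees = hp$num_trees, max.depth = hp$max_depth,
    min.node.size = hp$min_split, min.bucket = hp$min_leaf,
    seed = seed, num.threads = num_threads, verbose = FALSE
  )
}

#' Tune and fit the Random-Forest risk model
#'
#' Selects hyperparameters maximising mean cross-validated AUC over a declared
#' grid (endpoints and midpoints of the search ranges), evaluated with
#' stratified k-fold cross-validation on a stratified subsample of the
#' training rows, then refits on the full training data with the selected
#' configuration. Deterministic for a fixed seed; ties broken by grid order.
#'
#' @param x complete numeric data.frame/matrix of training features.
#' @param y 0/1 training outcomes.
#' @param ranges hyperparameter ranges, see [hyper_ranges()]. A length-1
#'   entry pins that hyperparameter (a single-point grid selects itself).
#' @param grid_points grid values per hyperparameter (default 3:
#'   endpoints + midpoint).
#' @param cv_folds number of stratified folds (default 5).
#' @param subsample_n tuning-subsample size; defaults to 12.1% of the training
#'   rows, capped at 50,000.
#' @param seed integer seed.
#' @param num_threads threads for the ranger backend (default 1).
#' @return an object of class `risk_model` exposing [predict_risk()].
#' @export
tune_and_fit <- function(x, y, ranges = hyper_ranges(), grid_points = 3,
                         cv_folds = 5, subsample_n = NULL, seed = 1,
                         num_threads = 1) {
  x <- as.data.frame(x)
  if (anyNA(x)) pa_abort("training features must be complete", "invalid_input")
  y <- as.integer(y)
  n <- nrow(x)
  if (is.null(subsample_n)) subsample_n <- min(ceiling(0.121 * n), 50000L)
  subsample_n <- min(subsample_n, n)
  grid <- hyper_grid(ranges, grid_points)
  set.seed(derive_seed(seed, 1))
  sub <- if (subsample_n < n) strat_sample_idx(y, subsample_n) else seq_len(n)
  xs <- x[sub, , drop = FALSE]; ys <- y[sub]
  # stratified fold assignment
  fold <- integer(length(ys))
  for (cl in unique(ys)) {
    pool <- which(ys == cl)
    fold[pool] <- sample(rep_len(seq_len(cv_folds), length(pool)))
  }
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) == 1L) {
    cv_auc <- 0  # single-point grid selects itself; skip CV
  } else {
    for (g in seq_len(nrow(grid))) {
      aucs <- numeric(0)
      for (k in seq_len(cv_folds)) {
        tr <- fold != k; te <- !tr
        if (length(unique(ys[tr])) < 2 || length(unique(ys[te])) < 2) {
          warning(sprintf("fold %d degenerate; skipped", k))
          next
        }
        fit <- fit_ranger(xs[tr, , drop = FALSE], ys[tr], grid[g, ],
                          seed = derive_seed(seed, 100 + k), num_threads)
        pr <- stats::predict(fit, data = xs[te, , drop = FALSE],
                             num.threads = num_threads)$predictions[, "1"]
        aucs <- c(aucs, auc(ys[te], pr))
      }
      if (length(aucs) == 0) pa_abort("all cross-validation folds degenerate", "cv_failure")
      cv_auc[g] <- mean(aucs)
    }
  }
  best <- which.max(cv_auc)
  hp <- as.list(grid[best, ])
  fit <- fit_ranger(x, y, hp, seed = derive_seed(seed, 2), num_threads)
  structure(
    list(fit = fit, feature_names = colnames(x), hyperparameters = hp,
         training_meta = list(n_train = n, cv_folds = cv_folds,
                              subsample_n = subsample_n, seed = seed,
                              grid_size = nrow(grid), cv_auc = cv_auc[best]),
         num_threads = num_threads),
    class = "risk_model"
  )
}

#' Predicted complication risk
#'
#' Uniform prediction contract for every interpretability stage: probabilities
#' in `(0, 1)` (clipped at `1e-6`), deterministic given a fitted model, one
#' value per input row.
#'
#' @param model a fitted model (e.g. a `risk_model`).
#' @param newdata data.frame/matrix of rows to score; extra columns are
#'   ignored, missing model features are an error.
#' @param ... passed to methods.
#' @return numeric vector of clipped probabilities.
#' @export
predict_risk <- function(model, newdata, ...) UseMethod("predict_risk")

#' @rdname predict_risk
#' @export
predict_risk.risk_model <- function(model, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(model$feature_names, names(newdata))
  if (length(missing)) {
    pa_abort(paste("missing feature(s):", paste(missing, collapse = ", ")),
             "unknown_feature")
  }
  pr <- stats::predict(model$fit, data = newdata[model$feature_names],
                       num.threads = model$num_threads)$predictions[, "1"]
  clip_prob(pr)
}

#' @export
print.risk_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("<risk_model> %d features, %d trees (depth %d, split %d, leaf %d), n_train %d\n",
              length(x$feature_names), hp$num_trees, hp$max_depth,
              hp$min_split, hp$min_leaf, x$training_meta$n_train))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random event case outranks a random
#' non-event case, with ties counted one half (mid-rank formula).
#'
#' @param labels 0/1 outcome vector.
#' @param scores numeric scores, higher = more event-like.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) pa_abort("AUC undefined: single-class input", "undefined_auc")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' @param labels,scores as in [auc()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return named vector `c(lower, upper)` with attribute `"point"`.
#' @export
auc_ci <- function(labels, scores, B = 1000, seed = 1, level = 0.95) {
  point <- auc(labels, scores)
  set.seed(seed)
  n <- length(labels)
  boots <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) next
    boots[b] <- auc(labels[idx], scores[idx])
  }
  boots <- boots[!is.na(boots)]
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(c(lower = qs[1], upper = qs[2]), point = point)
}

#' Interaction model over base features
#'
#' Wraps a model fitted on main effects plus product columns so it can be
#' queried with base-feature rows only: interaction columns are rebuilt from
#' the stored standardisation statistics before every prediction. This keeps
#' partial-dependence clamping consistent — moving a base feature moves every
#' product it participates in.
#'
#' @param model a `risk_model` fitted on the widened (main + product) table.
#' @param ispec the [make_interaction_spec()] used to widen it.
#' @return an object of class `interaction_risk_model`.
#' @export
interaction_risk_model <- function(model, ispec) {
  structure(list(model = model, ispec = ispec), class = "interaction_risk_model")
}

#' @rdname predict_risk
#' @export
predict_risk.interaction_risk_model <- function(model, newdata, ...) {
  widened <- build_interaction_features(as.data.frame(newdata), model$ispec)
  predict_risk(model$model, widened)
}
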