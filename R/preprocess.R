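# Preprocessing: sentinel recoding, physiologic filters, imputation, split.

#' Recode sentinel codes and registry tokens to proper missing values
#'
#' `"90+"` age tokens become the numeric value 90 (they are *not* missing);
#' sentinel codes (e.g. -99, -1, as declared per feature) become `NA` with the
#' missingness mask updated; all other cells are unchanged. After recoding,
#' every column is numeric.
#'
#' @param cohort a [cohort_table()].
#' @return the recoded cohort.
#' @export
recode_sentinels <- function(cohort) {
  data <- cohort$data
  mask <- cohort$missing_mask
  for (nm in names(data)) {
    col <- data[[nm]]
    sent <- cohort$specs[[nm]]$sentinel_codes
    if (is.character(col)) {
      col <- trimws(col)
      out <- suppressWarnings(as.numeric(col))
      out[col == "90+"] <- 90
      is_sent <- col %in% as.character(sent) | (!is.na(out) & out %in% sent)
      out[is_sent] <- NA_real_
      bad <- which(is.na(out) & !is_sent & !(is.na(col) | col == "" | col == "90+"))
      if (length(bad)) {
        pa_abort(sprintf("cannot parse value '%s' at row %d, column '%s'",
                         col[bad[1]], bad[1], nm), "parse_error")
      }
      data[[nm]] <- out
    } else {
      col[col %in% sent] <- NA_real_
      data[[nm]] <- col
    }
    mask[, nm] <- mask[, nm] | is.na(data[[nm]])
  }
  cohort$data <- data
  cohort$missing_mask <- mask
  cohort
}

# keep a subset of rows, preserving all parallel structures
cohort_subset <- function(cohort, keep) {
  cohort$data <- cohort$data[keep, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort$outcome <- cohort$outcome[keep]
  cohort$missing_mask <- cohort$missing_mask[keep, , drop = FALSE]
  cohort
}

#' Remove biologically implausible rows
#'
#' Applies each feature's declared physiologic range sequentially (spec
#' order): a row is removed when the observed value falls strictly outside
#' `[low, high]`; values exactly at a bound are retained, and missing values
#' never trigger removal. Rules are idempotent — a second application removes
#' nothing.
#'
#' @param cohort a recoded [cohort_table()] (no character columns).
#' @return `list(cohort = filtered cohort, report = data.frame)` where the
#'   report has one row per rule: `rule`, `low`, `high`, `n_removed`.
#' @export
apply_physiologic_filters <- function(cohort) {
  if (any(vapply(cohort$data, is.character, logical(1)))) {
    pa_abort("sentinels must be recoded before filtering", "invalid_input")
  }
  rules <- Filter(function(s) !is.null(s$physiologic_range), cohort$specs)
  report <- data.frame(rule = character(0), low = numeric(0), high = numeric(0),
                       n_removed = integer(0), stringsAsFactors = FALSE)
  for (s in rules) {
    col <- cohort$data[[s$name]]
    lo <- s$physiologic_range[1]; hi <- s$physiologic_range[2]
    viol <- !is.na(col) & (col < lo | col > hi)
    report <- rbind(report, data.frame(rule = paste0(s$name, "_range"),
                                       low = lo, high = hi,
                                       n_removed = sum(viol),
                                       stringsAsFactors = FALSE))
    if (any(viol)) cohort <- cohort_subset(cohort, !viol)
  }
  list(cohort = cohort, report = report)
}

#' Median imputation with explicit missing categories
#'
#' Continuous features: missing cells are replaced by the median computed over
#' the *fitting* rows only (typically the training partition, so no test
#' leakage). Binary and ordinal features: missing cells become an explicit
#' "missing" category coded as `max(levels) + 1` — the treatment used for the
#' two high-missingness categoricals (elective status, weight loss) and
#' applied uniformly to any other categorical missing cell.
#'
#' @param cohort a recoded [cohort_table()].
#' @param fit_ids row indices the medians are computed from (non-empty).
#' @return the imputed cohort (no `NA` cells remain; the missingness mask
#'   still records which cells were originally missing).
#' @export
impute_median <- function(cohort, fit_ids) {
  if (length(fit_ids) == 0) pa_abort("fit_ids must be non-empty", "invalid_input")
  for (nm in names(cohort$data)) {
    col <- cohort$data[[nm]]
    if (!anyNA(col)) next
    spec <- cohort$specs[[nm]]
    if (spec$kind == "continuous") {
      obs <- col[fit_ids]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) {
        pa_abort(sprintf("feature '%s' entirely missing over fitting rows", nm),
                 "imputation_failure")
      }
      col[is.na(col)] <- stats::median(obs)
    } else {
      col[is.na(col)] <- max(spec$levels) + 1
    }
    cohort$data[[nm]] <- col
  }
  cohort
}

#' Chained-equations multiple imputation
#'
#' Produces `m` complete datasets by iterative conditional regression
#' imputation: linear regression with a stochastic residual draw for
#' continuous targets, logistic regression with a Bernoulli draw for binary
#' targets, and linear regression rounded to the nearest declared level for
#' ordinal targets. Features are visited in descending order of missing rate
#' for a fixed number of sweeps; conditional models are fitted on the fitting
#' rows with the target observed, using the current completed values of all
#' other features as predictors. A singular or non-converged conditional fit
#' falls back to median/mode filling for that feature (recorded in the
#' `"fallbacks"` attribute). Identical seeds give identical output.
#'
#' @param cohort a recoded [cohort_table()].
#' @param fit_ids row indices conditional models are fitted on.
#' @param m number of imputed datasets (>= 2), default 5.
#' @param seed integer seed; dataset `i` uses `derive_seed(seed, i)`.
#' @param sweeps number of full passes over the incomplete features.
#' @return a list of `m` complete [cohort_table()] objects.
#' @export
impute_chained <- function(cohort, fit_ids, m = 5, seed = 1, sweeps = 10) {
  if (m < 2) pa_abort("m must be at least 2", "invalid_input")
  if (length(fit_ids) == 0) pa_abort("fit_ids must be non-empty", "invalid_input")
  data0 <- as.matrix(cohort$data)
  if (!is.numeric(data0)) pa_abort("recode sentinels before imputation", "invalid_input")
  miss_rate <- colMeans(is.na(data0))
  if (all(miss_rate == 0)) {
    return(replicate(m, cohort, simplify = FALSE))
  }
  targets <- names(sort(miss_rate[miss_rate > 0], decreasing = TRUE))
  # simple starting fill: median (continuous) / most frequent level (other)
  start_fill <- function(mat) {
    for (nm in colnames(mat)) {
      col <- mat[, nm]
      if (!anyNA(col)) next
      obs <- col[fit_ids]; obs <- obs[!is.na(obs)]
      if (length(obs) == 0) {
        pa_abort(sprintf("feature '%s' entirely missing over fitting rows", nm),
                 "imputation_failure")
      }
      fill <- if (cohort$specs[[nm]]$kind == "continuous") {
        stats::median(obs)
      } else {
        as.numeric(names(which.max(table(obs))))
      }
      col[is.na(col)] <- fill
      mat[, nm] <- col
    }
    mat
  }
  out <- vector("list", m)
  fallbacks <- character(0)
  for (imp in seq_len(m)) {
    set.seed(derive_seed(seed, imp))
    cur <- start_fill(data0)
    for (sw in seq_len(sweeps)) {
      for (nm in targets) {
        idx_miss <- which(is.na(data0[, nm]))
        idx_obs <- intersect(fit_ids, which(!is.na(data0[, nm])))
        X <- cbind(1, cur[, setdiff(colnames(cur), nm), drop = FALSE])
        spec <- cohort$specs[[nm]]
        drawn <- NULL
        ok <- TRUE
        if (spec$kind == "binary") {
          fit <- tryCatch(
            suppressWarnings(stats::glm.fit(X[idx_obs, , drop = FALSE],
                                            data0[idx_obs, nm],
                                            family = stats::binomial())),
            error = function(e) NULL)
          if (is.null(fit) || anyNA(fit$coefficients)) {
            ok <- FALSE
          } else {
            pr <- stats::plogis(X[idx_miss, , drop = FALSE] %*% fit$coefficients)
            drawn <- stats::rbinom(length(idx_miss), 1L, pr)
          }
        } else {
          fit <- stats::lm.fit(X[idx_obs, , drop = FALSE], data0[idx_obs, nm])
          if (fit$rank < ncol(X)) {
            ok <- FALSE
          } else {
            sigma <- sqrt(sum(fit$residuals^2) /
                            max(length(idx_obs) - fit$rank, 1))
            mu <- X[idx_miss, , drop = FALSE] %*% fit$coefficients
            drawn <- stats::rnorm(length(idx_miss), mu, sigma)
            if (spec$kind == "ordinal") {
              lev <- spec$levels
              drawn <- lev[pmin(pmax(round(drawn), min(lev)), max(lev)) - min(lev) + 1]
            }
          }
        }
        if (!ok) {
          fallbacks <- c(fallbacks, sprintf("imp %d sweep %d: %s (median/mode fallback)",
                                            imp, sw, nm))
          obs <- data0[idx_obs, nm]
          fill <- if (spec$kind == "continuous") stats::median(obs) else
            as.numeric(names(which.max(table(obs))))
          drawn <- rep(fill, length(idx_miss))
        }
        cur[idx_miss, nm] <- drawn
      }
    }
    imp_cohort <- cohort
    imp_cohort$data <- as.data.frame(cur)
    out[[imp]] <- imp_cohort
  }
  attr(out, "fallbacks") <- unique(fallbacks)
  out
}

#' Outcome-stratified train/test split
#'
#' Allocates each outcome class independently at `train_fraction` (per-class
#' counts rounded to nearest, remainder to the training side), so the
#' complication rate is preserved to within one patient per class in both
#' partitions.
#'
#' @param outcome 0/1 outcome vector, or a [cohort_table()].
#' @param train_fraction proportion of rows allocated to training.
#' @param seed integer seed.
#' @return an object of class `split_indices`: `train_ids`, `test_ids`,
#'   `train_fraction`, `outcome_rate_train`, `outcome_rate_test`.
#' @export
stratified_split <- function(outcome, train_fraction = 0.8, seed = 1) {
  if (inherits(outcome, "cohort_table")) outcome <- outcome$outcome
  classes <- sort(unique(outcome))
  if (length(classes) < 2) pa_abort("both outcome classes must be present", "split_failure")
  if (any(table(outcome) < 2)) {
    pa_abort("each outcome class needs at least 2 members", "split_failure")
  }
  set.seed(seed)
  train_ids <- integer(0)
  for (cl in classes) {
    pool <- which(outcome == cl)
    n_tr <- floor(length(pool) * train_fraction + 0.5)
    n_tr <- min(max(n_tr, 1L), length(pool) - 1L)
    train_ids <- c(train_ids, sort(sample(pool, n_tr)))
  }
  train_ids <- sort(train_ids)
  test_ids <- setdiff(seq_along(outcome), train_ids)
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         train_fraction = train_fraction,
         outcome_rate_train = mean(outcome[train_ids]),
         outcome_rate_test = mean(outcome[test_ids])),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d (rate %.4f) / test %d (rate %.4f)\n",
              length(x$train_ids), x$outcome_rate_train,
              length(x$test_ids), x$outcome_rate_test))
  invisible(x)
}
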