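# Synthetic cohort generation: registry-like tables with known planted truth.

# inverse-CDF draw for one feature given uniforms in (0,1)
quantile_from_spec <- function(spec, u) {
  switch(spec$kind,
    continuous = {
      lo <- spec$sim_bounds[1]; hi <- spec$sim_bounds[2]
      plo <- stats::pnorm(lo, spec$mean, spec$sd)
      phi <- stats::pnorm(hi, spec$mean, spec$sd)
      stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
    },
    binary = as.numeric(stats::qbinom(u, 1L, spec$prevalence)),
    ordinal = spec$levels[as.integer(cut(u, breaks = c(0, cumsum(spec$probs)),
                                         labels = FALSE, include.lowest = TRUE))]
  )
}

# draw a complete (pre-missingness) n-by-p value matrix; assumes RNG is set.
# `correlation` optionally imposes a Gaussian copula on a named subset of
# features; remaining features are drawn independently in spec order.
draw_complete <- function(specs, n, correlation = NULL) {
  p <- length(specs)
  values <- matrix(NA_real_, n, p, dimnames = list(NULL, names(specs)))
  cor_feats <- character(0)
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), !is.null(rownames(correlation)),
              identical(rownames(correlation), colnames(correlation)))
    cor_feats <- rownames(correlation)
    unknown <- setdiff(cor_feats, names(specs))
    if (length(unknown)) {
      pa_abort(paste("correlation names unknown:", paste(unknown, collapse = ", ")),
               "unknown_feature")
    }
    z <- matrix(stats::rnorm(n * length(cor_feats)), n) %*% chol(correlation)
    u <- stats::pnorm(z)
    for (k in seq_along(cor_feats)) {
      nm <- cor_feats[k]
      values[, nm] <- quantile_from_spec(specs[[nm]], u[, k])
    }
  }
  for (nm in setdiff(names(specs), cor_feats)) {
    values[, nm] <- quantile_from_spec(specs[[nm]], stats::runif(n))
  }
  # registry convention: ages at or above 90 are coded "90+"; the numeric
  # truth used by the outcome model is capped at 90
  if ("age" %in% names(specs) && specs[["age"]]$kind == "continuous") {
    values[, "age"] <- pmin(values[, "age"], 90)
  }
  values
}

#' Construct a cohort table
#'
#' The rectangular patient-by-feature container used throughout the audit:
#' raw feature values (sentinel codes and `"90+"` tokens permitted), a binary
#' outcome, a missingness mask, the feature specifications, and provenance.
#'
#' @param data data.frame of feature columns (one per spec, same order).
#' @param outcome integer vector of 0/1 outcomes, one per row.
#' @param missing_mask logical matrix, `TRUE` where a value is missing or
#'   sentinel-coded.
#' @param specs named list of [feature_spec()] objects.
#' @param provenance list describing origin (synthetic seed + ground truth, or
#'   external file).
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(data, outcome, missing_mask, specs, provenance = list()) {
  stopifnot(is.data.frame(data), nrow(data) == length(outcome),
            all(outcome %in% c(0L, 1L)),
            identical(dim(missing_mask), dim(as.matrix(data))),
            identical(names(data), names(specs)))
  structure(
    list(data = data, outcome = as.integer(outcome),
         missing_mask = missing_mask, specs = specs, provenance = provenance),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients x %d features, outcome prevalence %.3f\n",
              nrow(x$data), ncol(x$data), mean(x$outcome)))
  miss <- colMeans(x$missing_mask)
  miss <- miss[miss > 0]
  if (length(miss)) {
    cat("  missing:", paste(sprintf("%s %.1f%%", names(miss), 100 * miss),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a synthetic registry-like cohort
#'
#' Draws complete covariates from the declared marginals (truncated normals
#' for continuous features, declared category distributions otherwise), draws
#' the binary 30-day outcome from the calibrated logistic ground truth applied
#' to the complete values, then degrades the table the way registry extracts
#' are degraded: a small fraction of biologically implausible values is
#' injected into the physiologically-filtered variables, completely-at-random
#' missingness is stamped in as sentinel codes, and ages of 90 or more are
#' emitted as the literal token `"90+"`. Identical arguments give a
#' byte-identical cohort.
#'
#' @param specs named list of [feature_spec()] objects.
#' @param gt calibrated `ground_truth` (see [calibrate_intercept()]).
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @param implausible_rate fraction of rows receiving one implausible value
#'   (default 0.5%), cycled uniformly over the filtered variables.
#' @param correlation optional named correlation matrix imposing a Gaussian
#'   copula on a subset of features (default independent draws).
#' @return a [cohort_table()].
#' @export
generate_cohort <- function(specs, gt, n, seed, implausible_rate = 0.005,
                            correlation = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    pa_abort("n must be a positive integer", "invalid_n")
  }
  n <- as.integer(n)
  if (is.na(gt$intercept)) {
    pa_abort("ground truth is uncalibrated; run calibrate_intercept() first",
             "uncalibrated")
  }
  set.seed(seed)
  values <- draw_complete(specs, n, correlation)
  eta <- gt$intercept + linear_predictor(gt, specs, values)
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))

  # implausible values exercise the physiologic filters; injected after the
  # outcome draw so the planted truth is unaffected
  filtered <- names(specs)[!vapply(specs, function(s) is.null(s$physiologic_range),
                                   logical(1))]
  pools <- list(
    bmi = c(5, 9, 85, 95),
    preop_hematocrit = c(8, 12, 62, 70),
    hemoglobin_a1c = c(1, 3, 22, 30),
    preop_albumin = c(0.2, 0.5, 6.8, 8),
    operative_time = c(760, 900, 1100, 1300)
  )
  n_bad <- round(implausible_rate * n)
  if (n_bad > 0 && length(filtered)) {
    rows <- sample.int(n, n_bad)
    vars <- filtered[1 + (seq_len(n_bad) - 1) %% length(filtered)]
    for (k in seq_len(n_bad)) {
      pool <- pools[[vars[k]]] %||% (specs[[vars[k]]]$physiologic_range[2] * 2)
      values[rows[k], vars[k]] <- pool[sample.int(length(pool), 1L)]
    }
  }

  mask <- matrix(FALSE, n, length(specs), dimnames = list(NULL, names(specs)))
  for (nm in names(specs)) {
    rate <- specs[[nm]]$missing_rate
    if (rate > 0) {
      miss <- stats::runif(n) < rate
      values[miss, nm] <- specs[[nm]]$sentinel_codes[1]
      mask[miss, nm] <- TRUE
    }
  }

  data <- as.data.frame(values)
  if ("age" %in% names(data)) {
    age_chr <- as.character(data$age)
    age_chr[values[, "age"] >= 90 & !mask[, "age"]] <- "90+"
    data$age <- age_chr
  }
  cohort_table(data, outcome, mask, specs,
               provenance = list(type = "synthetic", seed = seed,
                                 ground_truth = gt,
                                 implausible_rate = implausible_rate))
}

#' Write a cohort to delimited text with sidecars
#'
#' Writes `cohort.csv` (feature columns plus `outcome`; missing cells keep
#' their sentinel codes), `features.json` (the feature specifications), and —
#' for synthetic cohorts — `ground_truth.json`, so planted effects can be
#' recovered in validation studies.
#'
#' @param cohort a [cohort_table()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(cohort$data, outcome = cohort$outcome),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(cohort$specs, unclass),
                       file.path(dir, "features.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  gt <- cohort$provenance$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(list(intercept = gt$intercept,
                              main = as.list(gt$main),
                              interactions = gt$interactions,
                              target_prevalence = gt$target_prevalence),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or any external cohort in the
#' same layout)
#'
#' @param dir directory containing `cohort.csv` and `features.json`.
#' @return a [cohort_table()]; the missing mask is rebuilt from sentinel codes
#'   and empty cells.
#' @export
read_cohort <- function(dir) {
  raw <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  sj <- jsonlite::read_json(file.path(dir, "features.json"))
  specs <- lapply(sj, function(s) {
    feature_spec(name = s$name, kind = if (s$kind == "ordinal") "ordinal" else s$kind,
                 mean = s$mean, sd = s$sd,
                 levels = if (!is.null(s$levels)) unlist(s$levels),
                 probs = if (!is.null(s$probs)) unlist(s$probs),
                 prevalence = s$prevalence,
                 missing_rate = s$missing_rate %||% 0,
                 sentinel_codes = unlist(s$sentinel_codes),
                 physiologic_range = if (!is.null(s$physiologic_range)) unlist(s$physiologic_range),
                 expected_direction = s$expected_direction %||% 0L,
                 sim_bounds = if (!is.null(s$sim_bounds)) unlist(s$sim_bounds))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  outcome <- raw$outcome
  data <- raw[names(specs)]
  mask <- matrix(FALSE, nrow(data), ncol(data),
                 dimnames = list(NULL, names(data)))
  for (nm in names(specs)) {
    col <- data[[nm]]
    sent <- specs[[nm]]$sentinel_codes
    if (is.character(col)) {
      mask[, nm] <- is.na(col) | col == "" | col %in% as.character(sent)
    } else {
      mask[, nm] <- is.na(col) | col %in% sent
    }
  }
  prov <- list(type = "external", path = dir)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gj <- jsonlite::read_json(gt_path)
    inter <- NULL
    if (!is.null(gj$interactions)) {
      inter <- do.call(rbind, lapply(gj$interactions, function(r) {
        data.frame(a = r$a, b = r$b, coef = r$coef, stringsAsFactors = FALSE)
      }))
    }
    prov$ground_truth <- ground_truth_model(
      specs, unlist(gj$main), interactions = inter,
      intercept = gj$intercept, target_prevalence = gj$target_prevalence
    )
    prov$type <- "synthetic"
  }
  cohort_table(data, outcome, mask, specs, provenance = prov)
}
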