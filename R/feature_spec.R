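#' Declare a predictor for cohort simulation and auditing
#'
#' A feature specification carries everything the generator, the preprocessing
#' rules, and the concordance audit need to know about one predictor: its
#' distributional family, missingness behaviour, sentinel codes, physiologic
#' plausibility bounds, and the direction in which it is expected to move risk.
#'
#' @param name identifier (used as the column name).
#' @param kind one of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param mean,sd marginal mean and standard deviation (continuous only; `sd > 0`).
#' @param levels,probs category levels and their probabilities (ordinal only;
#'   probabilities must sum to 1 within 1e-9).
#' @param prevalence proportion of 1s in `[0, 1]` (binary only).
#' @param missing_rate completely-at-random missingness proportion in `[0, 1]`.
#' @param sentinel_codes numeric codes that encode "missing" in raw files
#'   (e.g. -99, -1).
#' @param physiologic_range length-2 `c(low, high)` plausibility bounds used by
#'   [apply_physiologic_filters()], or `NULL` when the feature is not filtered.
#'   Values strictly inside the bounds are retained; bounds themselves are kept.
#' @param expected_direction expected sign of the feature's marginal effect on
#'   risk: `+1`, `-1`, or `0` (unknown/none).
#' @param sim_bounds truncation bounds used when simulating a continuous
#'   feature (defaults to `mean +/- 6 sd`); ignored for other kinds.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name,
                         kind = c("continuous", "binary", "ordinal"),
                         mean = NULL, sd = NULL,
                         levels = NULL, probs = NULL,
                         prevalence = NULL,
                         missing_rate = 0,
                         sentinel_codes = c(-99, -1),
                         physiologic_range = NULL,
                         expected_direction = 0L,
                         sim_bounds = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (missing_rate < 0 || missing_rate > 1) {
    pa_abort(sprintf("missing_rate for '%s' must lie in [0, 1]", name), "invalid_spec")
  }
  if (!expected_direction %in% c(-1L, 0L, 1L)) {
    pa_abort(sprintf("expected_direction for '%s' must be -1, 0, or +1", name), "invalid_spec")
  }
  if (kind == "continuous") {
    stopifnot(is.numeric(mean), is.numeric(sd))
    if (sd <= 0) pa_abort(sprintf("sd for '%s' must be positive", name), "invalid_spec")
    if (is.null(sim_bounds)) sim_bounds <- c(mean - 6 * sd, mean + 6 * sd)
  } else if (kind == "binary") {
    stopifnot(is.numeric(prevalence))
    if (prevalence < 0 || prevalence > 1) {
      pa_abort(sprintf("prevalence for '%s' must lie in [0, 1]", name), "invalid_spec")
    }
    levels <- c(0, 1)
  } else {
    stopifnot(is.numeric(levels), is.numeric(probs), length(levels) == length(probs))
    if (abs(sum(probs) - 1) > 1e-9) {
      pa_abort(sprintf("probabilities for '%s' must sum to 1", name), "invalid_spec")
    }
  }
  if (!is.null(physiologic_range)) {
    stopifnot(length(physiologic_range) == 2L)
    if (physiologic_range[1] >= physiologic_range[2]) {
      pa_abort(sprintf("physiologic_range for '%s' must have low < high", name), "invalid_spec")
    }
  }
  structure(
    list(name = name, kind = kind, mean = mean, sd = sd,
         levels = levels, probs = probs, prevalence = prevalence,
         missing_rate = missing_rate, sentinel_codes = sentinel_codes,
         physiologic_range = physiologic_range,
         expected_direction = as.integer(expected_direction),
         sim_bounds = sim_bounds),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s (%s)", x$name, x$kind))
  if (x$kind == "continuous") cat(sprintf(" mean %.3g sd %.3g", x$mean, x$sd))
  if (x$kind == "binary") cat(sprintf(" prevalence %.3g", x$prevalence))
  if (x$missing_rate > 0) cat(sprintf(" missing %.1f%%", 100 * x$missing_rate))
  cat(sprintf(" direction %+d\n", x$expected_direction))
  invisible(x)
}

# theoretical mean/sd used for z-standardisation inside the generating model
spec_moments <- function(spec) {
  switch(spec$kind,
    continuous = c(mean = spec$mean, sd = spec$sd),
    binary = c(mean = spec$prevalence,
               sd = sqrt(max(spec$prevalence * (1 - spec$prevalence), 1e-12))),
    ordinal = {
      m <- sum(spec$levels * spec$probs)
      v <- sum(spec$probs * (spec$levels - m)^2)
      c(mean = m, sd = sqrt(max(v, 1e-12)))
    }
  )
}

#' Default feature specifications emulating a national TJA registry cohort
#'
#' Twenty predictors — demographics, comorbidities, preoperative labs, and
#' surgical factors — with marginal distributions, missingness rates, sentinel
#' codes, physiologic plausibility bounds, and expected risk directions
#' matching the summary statistics reported for a 517,826-case national
#' surgical-registry total-joint-arthroplasty cohort. Diabetes is coded
#' ordinally (0 none, 1 non-insulin-dependent, 2 insulin-dependent) and ASA
#' physical status 1-5; ages at or above 90 are emitted as the literal token
#' `"90+"` in raw files, mirroring registry coding.
#'
#' @return a named list of 20 [feature_spec()] objects.
#' @export
default_nsqip_specs <- function() {
  asa_counts <- c(9568, 242181, 254926, 10424, 34)
  asa_probs <- asa_counts / sum(asa_counts)
  # diabetes: 16.4% overall, split 2:1 non-insulin : insulin-dependent
  dm_probs <- c(1 - 0.164, 0.164 * 2 / 3, 0.164 / 3)
  specs <- list(
    feature_spec("age", "continuous", mean = 67.0, sd = 10.0,
                 expected_direction = +1, sim_bounds = c(18, Inf)),
    feature_spec("sex_female", "binary", prevalence = 0.583, expected_direction = -1),
    feature_spec("bmi", "continuous", mean = 31.8, sd = 6.5,
                 physiologic_range = c(10, 80), expected_direction = +1,
                 sim_bounds = c(12, 70)),
    feature_spec("diabetes", "ordinal", levels = c(0, 1, 2), probs = dm_probs,
                 expected_direction = -1),
    feature_spec("smoking", "binary", prevalence = 0.085, expected_direction = +1),
    feature_spec("functional_dependent", "binary", prevalence = 0.020,
                 expected_direction = -1),
    feature_spec("hypertension", "binary", prevalence = 0.600, expected_direction = +1),
    feature_spec("copd", "binary", prevalence = 0.034, expected_direction = +1),
    feature_spec("chf", "binary", prevalence = 0.018, expected_direction = +1),
    feature_spec("steroid_use", "binary", prevalence = 0.040, expected_direction = +1),
    feature_spec("weight_loss", "binary", prevalence = 0.001, missing_rate = 0.607,
                 sentinel_codes = -1, expected_direction = -1),
    feature_spec("bleeding_disorder", "binary", prevalence = 0.019,
                 expected_direction = +1),
    feature_spec("preop_hematocrit", "continuous", mean = 41.4, sd = 4.1,
                 missing_rate = 0.066, sentinel_codes = c(-99, -1),
                 physiologic_range = c(15, 60), expected_direction = -1,
                 sim_bounds = c(20, 60)),
    feature_spec("preop_creatinine", "continuous", mean = 0.9, sd = 0.4,
                 missing_rate = 0.074, sentinel_codes = c(-99, -1),
                 expected_direction = +1, sim_bounds = c(0.2, 8)),
    feature_spec("hemoglobin_a1c", "continuous", mean = 5.9, sd = 0.9,
                 missing_rate = 0.902, sentinel_codes = c(-99, -1),
                 physiologic_range = c(4, 20), expected_direction = -1,
                 sim_bounds = c(4, 16)),
    feature_spec("preop_albumin", "continuous", mean = 4.2, sd = 0.4,
                 missing_rate = 0.449, sentinel_codes = c(-99, -1),
                 physiologic_range = c(1, 6), expected_direction = -1,
                 sim_bounds = c(1.5, 6)),
    feature_spec("asa_class", "ordinal", levels = 1:5, probs = asa_probs,
                 expected_direction = +1),
    feature_spec("operative_time", "continuous", mean = 90.9, sd = 35.6,
                 physiologic_range = c(0, 720), expected_direction = +1,
                 sim_bounds = c(15, 600)),
    feature_spec("elective", "binary", prevalence = 0.979, missing_rate = 0.607,
                 sentinel_codes = -1, expected_direction = -1),
    feature_spec("procedure_tha", "binary", prevalence = 0.407, expected_direction = +1)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
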