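# PDP-SHAP directional concordance validation.

#' Spearman rank correlation with mid-rank ties and t-approximate p-value
#'
#' Thin, contract-checked wrapper around [stats::cor.test()]
#' (`method = "spearman"`, asymptotic): mid-rank tie handling, two-tailed
#' p-value from the t-approximation on `n - 2` degrees of freedom. Constant
#' input raises a `degenerate_correlation` error rather than returning `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    pa_abort("x and y must have equal length >= 3", "invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pa_abort("correlation undefined for constant input", "degenerate_correlation")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Bonferroni-corrected significance level
#'
#' @param family_alpha family-wise error rate (e.g. 0.05).
#' @param m number of comparisons (>= 1).
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (m < 1) pa_abort("m must be >= 1", "invalid_input")
  family_alpha / m
}

#' Pooled directional-agreement percentages
#'
#' Unweighted agreement is the simple percentage of agreeing features;
#' weighted agreement weights each feature by its (non-negative) importance,
#' typically the permutation relative influence. With equal weights the two
#' coincide, and the weighted figure is invariant to rescaling all weights by
#' a positive constant.
#'
#' @param agrees logical vector of per-feature agreement flags.
#' @param weights optional non-negative weights (default equal).
#' @return list with `unweighted` and `weighted`, both in percent.
#' @export
agreement_summary <- function(agrees, weights = NULL) {
  stopifnot(is.logical(agrees), length(agrees) > 0)
  if (is.null(weights)) weights <- rep(1, length(agrees))
  stopifnot(length(weights) == length(agrees), all(weights >= 0))
  list(
    unweighted = 100 * mean(agrees),
    weighted = if (sum(weights) > 0) 100 * sum(weights[agrees]) / sum(weights) else NA_real_
  )
}

#' PDP-SHAP directional concordance report
#'
#' For each feature, compares the sign of its partial-dependence trend with
#' the sign of the Spearman correlation between the feature's values and its
#' per-patient Shapley attributions over a patient sample. A feature agrees
#' when both signs are nonzero and equal; a flat (zero-sign) PDP is counted as
#' non-agreeing and flagged, as is a degenerate (constant-input) correlation.
#' Pooled agreement is reported unweighted and weighted by permutation
#' relative influence, alongside the Bonferroni-corrected per-feature alpha.
#'
#' @param directions list of [trend_direction()] results (or a data.frame with
#'   `feature`, `slope_sign`), one per audited feature.
#' @param attrib an [shapley_attributions()] result for the patient sample.
#' @param feature_values data.frame of the same patients' feature values
#'   (rows aligned with `attrib`).
#' @param weights an `importance_records` data.frame (or named numeric
#'   vector); negative importances are floored at zero.
#' @param family_alpha family-wise error rate (default 0.05).
#' @return an object of class `concordance_report`: per-feature `rows`
#'   (`feature`, `pdp_sign`, `rho`, `p_value`, `agrees`, `importance_weight`,
#'   `flag`), `n_patients_sampled`, `unweighted_agreement`,
#'   `weighted_agreement`, `alpha_corrected`.
#' @export
concordance_report <- function(directions, attrib, feature_values, weights,
                               family_alpha = 0.05) {
  if (is.data.frame(directions)) {
    dir_df <- directions[c("feature", "slope_sign")]
  } else {
    dir_df <- data.frame(
      feature = vapply(directions, `[[`, character(1), "feature"),
      slope_sign = vapply(directions, `[[`, integer(1), "slope_sign"),
      stringsAsFactors = FALSE
    )
  }
  feature_values <- as.data.frame(feature_values)
  if (nrow(feature_values) != nrow(attrib$values)) {
    pa_abort("feature_values and attributions must cover the same patients",
             "alignment_error")
  }
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$relative_influence, weights$feature)
  } else {
    w <- weights
  }
  rows <- NULL
  for (i in seq_len(nrow(dir_df))) {
    f <- dir_df$feature[i]
    if (!f %in% attrib$feature_names) {
      pa_abort(paste("feature missing from attributions:", f), "alignment_error")
    }
    if (!f %in% names(feature_values)) {
      pa_abort(paste("feature missing from patient sample:", f), "alignment_error")
    }
    if (!f %in% names(w)) {
      pa_abort(paste("feature missing from importance weights:", f), "alignment_error")
    }
    flag <- ""
    rho <- NA_real_; pval <- NA_real_
    res <- tryCatch(spearman_cor(feature_values[[f]], attrib$values[, f]),
                    degenerate_correlation = function(e) NULL)
    if (is.null(res)) {
      flag <- "degenerate_correlation"
    } else {
      rho <- res$rho; pval <- res$p_value
    }
    pdp_sign <- dir_df$slope_sign[i]
    if (pdp_sign == 0L) flag <- paste0(flag, if (nzchar(flag)) ";", "flat_pdp")
    agrees <- !is.na(rho) && pdp_sign != 0L && sign(rho) != 0 &&
      sign(rho) == pdp_sign
    rows <- rbind(rows, data.frame(
      feature = f, pdp_sign = pdp_sign, rho = rho, p_value = pval,
      agrees = agrees, importance_weight = max(w[[f]], 0), flag = flag,
      stringsAsFactors = FALSE
    ))
  }
  pooled <- agreement_summary(rows$agrees, rows$importance_weight)
  structure(
    list(rows = rows, n_patients_sampled = nrow(feature_values),
         unweighted_agreement = pooled$unweighted,
         weighted_agreement = pooled$weighted,
         alpha_corrected = bonferroni_alpha(family_alpha, nrow(rows))),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d features over %d patients\n",
              nrow(x$rows), x$n_patients_sampled))
  cat(sprintf("  agreement: unweighted %.1f%%, importance-weighted %.1f%% (alpha = %.4g)\n",
              x$unweighted_agreement, x$weighted_agreement, x$alpha_corrected))
  invisible(x)
}
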