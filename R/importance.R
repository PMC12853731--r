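# Permutation importance, relative-influence thresholding, VIF.

#' Repeated permutation importance
#'
#' For each feature, the evaluation-set AUC drop (baseline AUC minus AUC after
#' shuffling that column) is measured over `repeats` independent within-column
#' shuffles of the fixed evaluation set (no row resampling). Relative
#' influence is each feature's positive mean drop as a fraction of the summed
#' positive mean drops; negative mean drops are retained in the records but
#' contribute zero to the normalisation.
#'
#' @param model a fitted model exposing [predict_risk()].
#' @param data complete evaluation features (data.frame).
#' @param outcome 0/1 evaluation outcomes (both classes present).
#' @param repeats number of shuffles per feature (default 30).
#' @param seed integer seed; feature `j` draws its shuffles from
#'   `derive_seed(seed, j)`.
#' @param chunk_rows maximum stacked rows per prediction call (memory guard).
#' @return data.frame of class `importance_records`: `feature`, `mean_drop`,
#'   `sd_drop`, `relative_influence`, `is_interaction` (from the `_x_` naming
#'   convention), with the baseline AUC as attribute `"baseline_auc"`.
#' @export
permutation_importance <- function(model, data, outcome, repeats = 30, seed = 1,
                                   chunk_rows = 200000) {
  data <- as.data.frame(data)
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2) {
    pa_abort("evaluation outcome must contain both classes", "undefined_auc")
  }
  if (repeats < 1) pa_abort("repeats must be >= 1", "invalid_input")
  n <- nrow(data)
  base_auc <- auc(outcome, predict_risk(model, data))
  feats <- colnames(data)
  per_chunk <- max(1L, floor(chunk_rows / n))
  mean_drop <- sd_drop <- numeric(length(feats))
  for (j in seq_along(feats)) {
    set.seed(derive_seed(seed, j))
    perms <- replicate(repeats, sample.int(n), simplify = FALSE)
    aucs <- numeric(repeats)
    done <- 0L
    while (done < repeats) {
      take <- seq(done + 1L, min(done + per_chunk, repeats))
      stacked <- data[rep(seq_len(n), length(take)), , drop = FALSE]
      col <- unlist(lapply(perms[take], function(p) data[[feats[j]]][p]))
      stacked[[feats[j]]] <- col
      pr <- predict_risk(model, stacked)
      for (k in seq_along(take)) {
        block <- ((k - 1L) * n + 1L):(k * n)
        aucs[take[k]] <- auc(outcome, pr[block])
      }
      done <- done + length(take)
    }
    drops <- base_auc - aucs
    mean_drop[j] <- mean(drops)
    sd_drop[j] <- stats::sd(drops)
  }
  pos <- pmax(mean_drop, 0)
  rel <- if (sum(pos) > 0) pos / sum(pos) else pos
  out <- data.frame(feature = feats, mean_drop = mean_drop, sd_drop = sd_drop,
                    relative_influence = rel,
                    is_interaction = grepl("_x_", feats, fixed = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "baseline_auc") <- base_auc
  class(out) <- c("importance_records", "data.frame")
  out
}

#' Threshold-based feature selection and influence decomposition
#'
#' Selects features whose relative influence exceeds the threshold (default
#' 5%) and decomposes influence by main-effect vs interaction status: the
#' shares of *total* model influence carried by selected interactions,
#' selected main effects, and the selected set overall, plus the
#' within-selected split.
#'
#' @param records an `importance_records` data.frame (or any data.frame with
#'   `feature`, `relative_influence`, `is_interaction`).
#' @param threshold relative-influence cut (default 0.05); selection is
#'   strictly greater-than.
#' @return an object of class `influence_decomposition` with fields
#'   `selected`, `share_interaction_total`, `share_main_total`,
#'   `share_selected_total`, `share_interaction_within`, `share_main_within`
#'   (all shares in percent).
#' @export
threshold_select <- function(records, threshold = 0.05) {
  stopifnot(nrow(records) > 0)
  sel <- records$relative_influence > threshold
  int_total <- 100 * sum(records$relative_influence[sel & records$is_interaction])
  main_total <- 100 * sum(records$relative_influence[sel & !records$is_interaction])
  sel_total <- int_total + main_total
  structure(
    list(selected = records[sel, , drop = FALSE],
         threshold = threshold,
         share_interaction_total = int_total,
         share_main_total = main_total,
         share_selected_total = sel_total,
         share_interaction_within = if (sel_total > 0) 100 * int_total / sel_total else 0,
         share_main_within = if (sel_total > 0) 100 * main_total / sel_total else 0),
    class = "influence_decomposition"
  )
}

#' @export
print.influence_decomposition <- function(x, ...) {
  cat(sprintf("<influence_decomposition> %d feature(s) above %.1f%% threshold\n",
              nrow(x$selected), 100 * x$threshold))
  cat(sprintf("  of total influence: interactions %.1f%%, main effects %.1f%%, selected %.1f%%\n",
              x$share_interaction_total, x$share_main_total, x$share_selected_total))
  cat(sprintf("  within selected: interactions %.1f%%, main effects %.1f%%\n",
              x$share_interaction_within, x$share_main_within))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of column `j`
#' on all other columns plus an intercept. Perfect collinearity is reported as
#' `Inf`, not an error. Median VIFs are reported overall and split into main
#' effects vs interaction columns (by the `_x_` naming convention unless
#' `interaction_cols` is given).
#'
#' @param x complete numeric data.frame/matrix with more rows than columns.
#' @param interaction_cols optional character vector naming the interaction
#'   columns.
#' @return list with `vif` (named vector), `median_main`,
#'   `median_interaction`, `median_overall`.
#' @export
vif <- function(x, interaction_cols = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) pa_abort("x must be complete", "invalid_input")
  if (nrow(x) <= ncol(x)) pa_abort("need n > p for VIF", "invalid_input")
  if (is.null(interaction_cols)) {
    interaction_cols <- colnames(x)[grepl("_x_", colnames(x), fixed = TRUE)]
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)  # constant column: inflation is unbounded
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  is_int <- names(out) %in% interaction_cols
  list(vif = out,
       median_main = if (any(!is_int)) stats::median(out[!is_int]) else NA_real_,
       median_interaction = if (any(is_int)) stats::median(out[is_int]) else NA_real_,
       median_overall = stats::median(out))
}
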