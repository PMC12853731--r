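# Monte-Carlo permutation-sampling Shapley attribution (interventional).

#' Per-patient Shapley attributions by Monte-Carlo permutation sampling
#'
#' For each patient, features are revealed one at a time in sampled random
#' orderings; each permutation is paired with one background row that supplies
#' the not-yet-revealed feature values (marginal/interventional completion,
#' ignoring feature dependence), with the pairing balanced so every background
#' row completes an equal share of the sampled orderings. A feature's raw attribution is
#' the average change in the model's log-odds prediction when it is revealed.
#' The additive residual against the patient's actual prediction is then
#' distributed proportionally to absolute raw attributions, so the efficiency
#' identity `base_value + sum(attributions) = log-odds prediction` holds
#' exactly for every patient. The base value is the mean log-odds prediction
#' over the full background.
#'
#' @param model a model exposing [predict_risk()].
#' @param background complete background data.frame (non-empty).
#' @param patients complete data.frame of patients to explain (same features).
#' @param n_permutations sampled orderings per patient (default 200).
#' @param seed integer seed.
#' @param chunk_rows maximum stacked rows per prediction call.
#' @return an object of class `attribution_matrix`: `values` (n x p matrix of
#'   log-odds attributions), `base_value`, `feature_names`, `patient_ids`,
#'   `prediction` (per-patient log-odds), `n_permutations`, `background_size`,
#'   `seed`.
#' @export
shapley_attributions <- function(model, background, patients,
                                 n_permutations = 200, seed = 1,
                                 chunk_rows = 200000) {
  background <- as.data.frame(background)
  patients <- as.data.frame(patients)
  if (nrow(background) == 0) pa_abort("background is empty", "invalid_input")
  if (n_permutations < 1) pa_abort("n_permutations must be >= 1", "invalid_input")
  feats <- colnames(background)
  if (!identical(sort(feats), sort(colnames(patients)))) {
    pa_abort("patients and background must share the same features", "unknown_feature")
  }
  patients <- patients[feats]
  p <- length(feats)
  n_pat <- nrow(patients)
  nb <- nrow(background)
  bg_mat <- as.matrix(background)

  base_value <- mean(stats::qlogis(predict_risk(model, background)))
  fx <- stats::qlogis(predict_risk(model, patients))
  if (any(!is.finite(fx)) || !is.finite(base_value)) {
    pa_abort("non-finite prediction encountered", "invalid_input")
  }

  # draw all orderings and paired background rows up front so results do not
  # depend on the prediction chunking
  set.seed(derive_seed(seed, 1))
  perm_list <- vector("list", n_pat)
  bgidx_list <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    perm_list[[i]] <- t(vapply(seq_len(n_permutations),
                               function(t) sample.int(p), integer(p)))
    # balanced pairing: every background row completes (nearly) the same
    # number of orderings, removing the background-sampling variance component
    bgidx_list[[i]] <- sample(rep_len(seq_len(nb), n_permutations))
  }

  rows_per_patient <- n_permutations * (p + 1)
  per_chunk <- max(1L, floor(chunk_rows / rows_per_patient))
  stage <- rep(0:p, n_permutations)
  values <- matrix(NA_real_, n_pat, p, dimnames = list(NULL, feats))

  build_x <- function(i) {
    perms <- perm_list[[i]]
    pos <- t(apply(perms, 1, order))          # step at which feature j is revealed
    posbig <- pos[rep(seq_len(n_permutations), each = p + 1), , drop = FALSE]
    reveal <- posbig <= stage                 # column-wise recycling over rows
    X <- bg_mat[rep(bgidx_list[[i]], each = p + 1), , drop = FALSE]
    patrow <- as.numeric(patients[i, ])
    patbig <- matrix(patrow, nrow = rows_per_patient, ncol = p, byrow = TRUE)
    X[reveal] <- patbig[reveal]
    X
  }

  done <- 0L
  while (done < n_pat) {
    take <- seq(done + 1L, min(done + per_chunk, n_pat))
    X <- do.call(rbind, lapply(take, build_x))
    preds <- stats::qlogis(predict_risk(model, X))
    for (k in seq_along(take)) {
      i <- take[k]
      block <- ((k - 1L) * rows_per_patient + 1L):(k * rows_per_patient)
      P <- matrix(preds[block], nrow = p + 1)  # one column per permutation
      D <- P[-1, , drop = FALSE] - P[-(p + 1), , drop = FALSE]
      feat_of_diff <- as.vector(t(perm_list[[i]]))
      raw <- as.numeric(rowsum(as.vector(D), feat_of_diff)) / n_permutations
      resid <- (fx[i] - base_value) - sum(raw)
      w <- abs(raw)
      values[i, ] <- raw + resid * (if (sum(w) > 0) w / sum(w) else rep(1 / p, p))
    }
    done <- done + length(take)
  }

  structure(
    list(values = values, base_value = base_value, feature_names = feats,
         patient_ids = rownames(patients) %||% as.character(seq_len(n_pat)),
         prediction = fx, n_permutations = n_permutations,
         background_size = nb, seed = seed),
    class = "attribution_matrix"
  )
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d patients x %d features (log-odds), base value %.4f, %d permutations\n",
              nrow(x$values), ncol(x$values), x$base_value, x$n_permutations))
  invisible(x)
}

#' Global importance ranking by mean absolute attribution
#'
#' @param attrib an [shapley_attributions()] result.
#' @return data.frame `feature`, `score` (mean |attribution| over patients),
#'   `rank`, sorted by descending score with alphabetical tie-break.
#' @export
mean_abs_importance <- function(attrib) {
  stopifnot(nrow(attrib$values) > 0)
  score <- colMeans(abs(attrib$values))
  ord <- order(-score, names(score))
  data.frame(feature = names(score)[ord], score = unname(score[ord]),
             rank = seq_along(score), stringsAsFactors = FALSE)
}
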