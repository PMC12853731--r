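# Archetype cases and end-to-end pipeline orchestration.

#' Select archetype patients at fixed risk percentiles
#'
#' Ranks patients by predicted risk and picks the patient at each target
#' percentile (nearest-rank definition, deterministic lowest-index tie-break),
#' then populates that patient's Shapley attributions and their position on
#' the population partial-dependence curve for each display feature (the
#' curve value at the patient's own feature value, computed by clamping —
#' not interpolated).
#'
#' @param model a model exposing [predict_risk()].
#' @param test_table complete data.frame of candidate patients (n >= 10).
#' @param background complete background data.frame for attributions and PDP
#'   positions.
#' @param percentiles risk percentiles to select at (default 10/50/90).
#' @param features display features (default hematocrit, age, operative time).
#' @param n_permutations Shapley permutations per case (default 200).
#' @param seed integer seed.
#' @param scale scale of the reported curve positions.
#' @return an object of class `archetype_cases`: one case per percentile with
#'   `patient_id`, `percentile`, `predicted_risk`, `feature_values`,
#'   `attributions`, `pdp_positions`.
#' @export
select_archetypes <- function(model, test_table, background,
                              percentiles = c(10, 50, 90),
                              features = c("preop_hematocrit", "age", "operative_time"),
                              n_permutations = 200, seed = 1,
                              scale = c("probability", "log-odds")) {
  scale <- match.arg(scale)
  test_table <- as.data.frame(test_table)
  n <- nrow(test_table)
  if (n < 10) pa_abort("need at least 10 patients to select archetypes", "insufficient_cohort")
  risk <- predict_risk(model, test_table)
  ord <- order(risk, seq_len(n))             # lowest-index tie-break
  ids <- vapply(percentiles, function(p) ord[max(1L, ceiling(p / 100 * n))], integer(1))
  attrib <- shapley_attributions(model, background, test_table[ids, , drop = FALSE],
                                 n_permutations = n_permutations, seed = seed)
  cases <- lapply(seq_along(ids), function(k) {
    i <- ids[k]
    pdp_pos <- do.call(rbind, lapply(features, function(f) {
      data.frame(feature = f, value = test_table[[f]][i],
                 curve_value = pdp_average(model, background, f,
                                           test_table[[f]][i], scale),
                 stringsAsFactors = FALSE)
    }))
    list(patient_id = i, percentile = percentiles[k], predicted_risk = risk[i],
         feature_values = as.list(test_table[i, , drop = FALSE]),
         attributions = attrib$values[k, ], pdp_positions = pdp_pos)
  })
  risks <- vapply(cases, `[[`, numeric(1), "predicted_risk")
  if (any(diff(risks) <= 0)) {
    warning("archetype risks are not strictly increasing across percentiles")
  }
  structure(list(cases = cases, percentiles = percentiles, risks = risks),
            class = "archetype_cases")
}

#' @export
print.archetype_cases <- function(x, ...) {
  cat("<archetype_cases>\n")
  for (case in x$cases) {
    cat(sprintf("  %dth percentile: patient %d, predicted risk %.3f\n",
                case$percentile, case$patient_id, case$predicted_risk))
  }
  invisible(x)
}

#' Pipeline configuration with declared defaults
#'
#' Returns the default configuration for [run_pipeline()]; any field can be
#' overridden by name. Problem-size fields (cohort size, importance repeats,
#' Shapley permutations, sample sizes) are the run-scale defaults discussed in
#' the methods vignette.
#'
#' @param ... named overrides.
#' @return a named list of class `audit_config`.
#' @export
audit_config <- function(...) {
  cfg <- list(
    n = 20000, seed = 1, implausible_rate = 0.005,
    correlation = NULL, calibrate_n = 50000,
    train_fraction = 0.8,
    ranges = hyper_ranges(), grid_points = 2, cv_folds = 5, tune_subsample = NULL,
    interaction_pairs = default_interaction_pairs(),
    threshold = 0.05, importance_repeats = 10, importance_eval_n = 4000,
    pdp_grid_size = 30, pdp_background_n = 1000,
    band_B = 50, band_m = 2000, band_grid = 15,
    surface_pairs = data.frame(
      a = c("age", "operative_time", "operative_time", "preop_hematocrit",
            "preop_hematocrit"),
      b = c("asa_class", "asa_class", "age", "asa_class", "diabetes"),
      stringsAsFactors = FALSE),
    surface_subsample = 2000, surface_grid = 15,
    shap_patients = 500, shap_permutations = 30, shap_background = 200,
    archetype_features = c("preop_hematocrit", "age", "operative_time"),
    family_alpha = 0.05,
    num_threads = 1,
    out_dir = NULL, write_cohort = FALSE, verbose = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    pa_abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")),
             "invalid_config")
  }
  cfg[names(over)] <- over
  class(cfg) <- "audit_config"
  cfg
}

#' Run the full interpretability audit end to end
#'
#' Generate -> recode -> filter -> split -> impute -> fit baseline and
#' interaction Random-Forest models -> permutation importance and threshold
#' decomposition -> PDP trend directions, 2D surfaces and bootstrap bands ->
#' Monte-Carlo Shapley attributions -> PDP-SHAP concordance -> archetype
#' cases -> VIF. Every stage draws its seed from the master seed through
#' [derive_seed()], so the whole run is reproducible and stages can be
#' re-executed in isolation. Artifacts (delimited tables and JSON reports)
#' are written to `config$out_dir` when set.
#'
#' @param config an [audit_config()].
#' @return the run summary (named list), invisibly also written as
#'   `summary.json` when an output directory is configured.
#' @export
run_pipeline <- function(config = audit_config()) {
  seed <- config$seed
  say <- function(stage, fmt, ...) {
    if (isTRUE(config$verbose)) {
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit_json <- function(obj, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(obj, file.path(out_dir, name),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  emit_csv <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }

  specs <- default_nsqip_specs()
  gt <- default_ground_truth(specs)
  gt$intercept <- calibrate_intercept(gt, specs, n_probe = config$calibrate_n,
                                      seed = derive_seed(seed, 1))
  say("calibrate", "intercept %.4f for target prevalence %.3f",
      gt$intercept, gt$target_prevalence)

  cohort <- generate_cohort(specs, gt, config$n, seed = derive_seed(seed, 2),
                            implausible_rate = config$implausible_rate,
                            correlation = config$correlation)
  if (isTRUE(config$write_cohort) && !is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }
  cohort <- recode_sentinels(cohort)
  fil <- apply_physiologic_filters(cohort)
  cohort <- fil$cohort
  emit_csv(fil$report, "filter_report.csv")
  say("preprocess", "%d rows retained after physiologic filters (removed: %s)",
      nrow(cohort$data), paste(fil$report$n_removed, collapse = "/"))

  split <- stratified_split(cohort$outcome, config$train_fraction,
                            seed = derive_seed(seed, 3))
  emit_json(list(n_train = length(split$train_ids), n_test = length(split$test_ids),
                 rate_train = split$outcome_rate_train,
                 rate_test = split$outcome_rate_test), "split.json")
  cohort <- impute_median(cohort, split$train_ids)
  x <- cohort$data
  y <- cohort$outcome
  tr <- split$train_ids; te <- split$test_ids

  baseline <- tune_and_fit(x[tr, ], y[tr], ranges = config$ranges,
                           grid_points = config$grid_points,
                           cv_folds = config$cv_folds,
                           subsample_n = config$tune_subsample,
                           seed = derive_seed(seed, 4),
                           num_threads = config$num_threads)
  test_pred <- predict_risk(baseline, x[te, ])
  test_auc <- auc(y[te], test_pred)
  test_ci <- auc_ci(y[te], test_pred, B = 200, seed = derive_seed(seed, 5))
  say("baseline", "test AUC %.4f [%.4f, %.4f]", test_auc, test_ci[1], test_ci[2])

  ispec <- make_interaction_spec(x, tr, config$interaction_pairs)
  xw <- build_interaction_features(x, ispec)
  inter_fit <- tune_and_fit(xw[tr, ], y[tr], ranges = config$ranges,
                            grid_points = config$grid_points,
                            cv_folds = config$cv_folds,
                            subsample_n = config$tune_subsample,
                            seed = derive_seed(seed, 6),
                            num_threads = config$num_threads)
  inter_model <- interaction_risk_model(inter_fit, ispec)
  inter_test_auc <- auc(y[te], predict_risk(inter_fit, xw[te, ]))
  say("interaction", "test AUC %.4f with %d features",
      inter_test_auc, ncol(xw))

  set.seed(derive_seed(seed, 7))
  eval_n <- min(config$importance_eval_n, length(te))
  eval_ids <- te[strat_sample_idx(y[te], eval_n)]
  imp_int <- permutation_importance(inter_fit, xw[eval_ids, ], y[eval_ids],
                                    repeats = config$importance_repeats,
                                    seed = derive_seed(seed, 8))
  decomp <- threshold_select(imp_int, config$threshold)
  emit_csv(as.data.frame(imp_int), "importance_interaction.csv")
  emit_json(list(threshold = decomp$threshold,
                 selected = decomp$selected$feature,
                 share_interaction_total = decomp$share_interaction_total,
                 share_main_total = decomp$share_main_total,
                 share_selected_total = decomp$share_selected_total,
                 share_interaction_within = decomp$share_interaction_within,
                 share_main_within = decomp$share_main_within),
            "decomposition.json")
  say("importance", "%d feature(s) above %.0f%% threshold; interactions carry %.1f%% of total influence",
      nrow(decomp$selected), 100 * config$threshold, decomp$share_interaction_total)

  imp_base <- permutation_importance(baseline, x[eval_ids, ], y[eval_ids],
                                     repeats = config$importance_repeats,
                                     seed = derive_seed(seed, 9))
  emit_csv(as.data.frame(imp_base), "importance_baseline.csv")

  set.seed(derive_seed(seed, 10))
  bg_ids <- tr[sort(sample.int(length(tr), min(config$pdp_background_n, length(tr))))]
  background <- x[bg_ids, ]
  directions <- vector("list", length(specs))
  curves_tbl <- NULL
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    cur <- if (s$kind == "continuous") {
      pdp_1d(baseline, background, s$name, grid_size = config$pdp_grid_size,
             scale = "log-odds")
    } else if (s$kind == "binary") {
      pdp_binary(baseline, background, s$name, scale = "log-odds")
    } else {
      pdp_levels(baseline, background, s$name, s$levels, scale = "log-odds")
    }
    directions[[k]] <- trend_direction(cur)
    curves_tbl <- rbind(curves_tbl,
                        data.frame(feature = s$name, grid = cur$grid,
                                   value = cur$values, stringsAsFactors = FALSE))
  }
  emit_csv(curves_tbl, "pdp_curves.csv")
  say("pdp", "trend directions computed for %d features over %d background rows",
      length(specs), nrow(background))

  surfaces <- lapply(seq_len(nrow(config$surface_pairs)), function(i) {
    pdp_2d(inter_model, background,
           c(config$surface_pairs$a[i], config$surface_pairs$b[i]),
           grid_size = config$surface_grid,
           n_subsample = min(config$surface_subsample, nrow(background)),
           seed = derive_seed(seed, 10 + i), scale = "log-odds")
  })
  bands <- lapply(config$archetype_features, function(f) {
    pdp_bootstrap_band(baseline, background, f, B = config$band_B,
                       m = config$band_m, seed = derive_seed(seed, 16),
                       grid_size = config$band_grid, scale = "probability")
  })

  set.seed(derive_seed(seed, 17))
  samp_ids <- te[sort(sample.int(length(te), min(config$shap_patients, length(te))))]
  set.seed(derive_seed(seed, 18))
  shap_bg <- x[tr[sort(sample.int(length(tr), min(config$shap_background, length(tr))))], ]
  attrib <- shapley_attributions(baseline, shap_bg, x[samp_ids, ],
                                 n_permutations = config$shap_permutations,
                                 seed = derive_seed(seed, 19))
  shap_rank <- mean_abs_importance(attrib)
  emit_csv(shap_rank, "shap_importance.csv")

  conc <- concordance_report(directions, attrib, x[samp_ids, ], imp_base,
                             family_alpha = config$family_alpha)
  emit_csv(conc$rows, "concordance.csv")
  say("concordance", "unweighted %.1f%%, weighted %.1f%% over %d patients",
      conc$unweighted_agreement, conc$weighted_agreement, conc$n_patients_sampled)

  archetypes <- select_archetypes(baseline, x[te, ], shap_bg,
                                  features = config$archetype_features,
                                  n_permutations = config$shap_permutations,
                                  seed = derive_seed(seed, 20))

  ztr <- scale(as.matrix(xw[tr, ]))
  keep <- apply(ztr, 2, function(c) all(is.finite(c)))
  vifres <- vif(ztr[, keep, drop = FALSE])
  emit_csv(data.frame(feature = names(vifres$vif), vif = vifres$vif,
                      stringsAsFactors = FALSE), "vif.csv")

  summary <- list(
    n_generated = config$n,
    n_after_filters = length(y),
    outcome_prevalence = mean(y),
    split = list(rate_train = split$outcome_rate_train,
                 rate_test = split$outcome_rate_test),
    baseline = list(hyperparameters = baseline$hyperparameters,
                    test_auc = test_auc,
                    test_auc_ci = as.numeric(test_ci)),
    interaction = list(hyperparameters = inter_fit$hyperparameters,
                       test_auc = inter_test_auc,
                       n_features = ncol(xw)),
    decomposition = list(
      selected = decomp$selected$feature,
      share_interaction_total = decomp$share_interaction_total,
      share_main_total = decomp$share_main_total,
      share_selected_total = decomp$share_selected_total,
      share_interaction_within = decomp$share_interaction_within,
      share_main_within = decomp$share_main_within),
    concordance = list(unweighted = conc$unweighted_agreement,
                       weighted = conc$weighted_agreement,
                       alpha_corrected = conc$alpha_corrected),
    archetype_risks = archetypes$risks,
    shap_top5 = utils::head(shap_rank$feature, 5),
    vif = list(median_main = vifres$median_main,
               median_interaction = vifres$median_interaction,
               median_overall = vifres$median_overall),
    n_surfaces = length(surfaces),
    n_bands = length(bands)
  )
  emit_json(summary, "summary.json")
  say("done", "pipeline complete")
  invisible(summary)
}
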