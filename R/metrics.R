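#' The fixed metric-vector schema
#'
#' Column names of the per-child feature battery: temporal parameters,
#' harmonic ratios, symmetry indices, Poincare variability of stride,
#' step and double-support series, multiscale sample entropy (scales 1-6,
#' three trunk axes), RQA summaries, and the retained clinical features.
#' Gestational age and birth weight are deliberately absent: they define
#' the high-risk label and must never be features.
#'
#' @return Character vector of feature names (excludes the id/label
#'   columns `child_id`, `group`, `risk`).
#' @export
metric_schema <- function() {
  c("strideT", "nstrideT", "stepT", "nstepT", "stanceT", "DS",
    "HR_v", "HR_ml", "HR_ap", "symm_stride", "symm_step",
    paste0(rep(c("strideT", "stepT", "DS"), each = 3),
           c("_SD1", "_SD2", "_std")),
    paste0("SEN_", rep(c("v", "ml", "ap"), each = 6), "_", 1:6),
    paste0(rep(c("RR", "DET", "AvgL"), each = 3), "_", c("v", "ml", "ap")),
    "sex", "twin", "length_birth_cm", "length_t24_cm", "weight_t24_g",
    "walk_exp_weeks", "cog_score")
}

clinical_feature_names <- function() {
  c("sex", "twin", "length_birth_cm", "length_t24_cm", "weight_t24_g",
    "walk_exp_weeks", "cog_score")
}

#' Assemble one metric vector
#'
#' Combines the temporal, variability, harmonic-ratio, entropy and RQA
#' blocks with the retained clinical features into a one-row data frame
#' with the fixed [metric_schema()] column order. Gestational age and
#' birth weight are rejected if passed as clinical features.
#'
#' @param temporal `temporal_params` object (or `NULL`).
#' @param variability Named list of `c(SD1, SD2, std)` vectors for
#'   `strideT`, `stepT`, `DS`.
#' @param HRs Named vector/list `HR_v`, `HR_ml`, `HR_ap`.
#' @param symm Named vector `symm_stride`, `symm_step`.
#' @param MSE Named list per axis (`v`, `ml`, `ap`) of scale-1..6 entropies.
#' @param RQA Named list per axis of `c(RR, DET, AvgL)`.
#' @param clinical One-row list/data.frame of retained clinical features.
#' @param child_id,group,risk Identity and label columns.
#' @return One-row `data.frame` with columns `child_id`, `group`, `risk`
#'   followed by [metric_schema()].
#' @export
assemble_metric_vector <- function(temporal, variability, HRs, symm,
                                   MSE, RQA, clinical,
                                   child_id = "anon", group = NA_character_,
                                   risk = NA_character_) {
  if (any(c("ga_weeks", "bw_g") %in% names(clinical)))
    abort_gw("gestational age and birth weight must not be features",
             "gaitwin_validation_error")
  row <- as.list(rep(NA_real_, length(metric_schema())))
  names(row) <- metric_schema()
  if (!is.null(temporal))
    for (f in c("strideT", "nstrideT", "stepT", "nstepT", "stanceT", "DS"))
      row[[f]] <- as.numeric(temporal[[f]])
  for (ax in c("v", "ml", "ap"))
    row[[paste0("HR_", ax)]] <- as.numeric(HRs[[paste0("HR_", ax)]] %||% NA_real_)
  row[["symm_stride"]] <- as.numeric(symm[["symm_stride"]])
  row[["symm_step"]] <- as.numeric(symm[["symm_step"]])
  for (p in names(variability))
    for (comp in c("SD1", "SD2", "std"))
      row[[paste0(p, "_", comp)]] <- as.numeric(variability[[p]][[comp]])
  for (ax in names(MSE))
    for (s in seq_along(MSE[[ax]]))
      row[[paste0("SEN_", ax, "_", s)]] <- as.numeric(MSE[[ax]][[s]])
  for (ax in names(RQA))
    for (comp in c("RR", "DET", "AvgL"))
      row[[paste0(comp, "_", ax)]] <- as.numeric(RQA[[ax]][[comp]])
  for (f in clinical_feature_names())
    if (!is.null(clinical[[f]])) row[[f]] <- clinical[[f]]
  df <- cbind(data.frame(child_id = child_id, group = group, risk = risk,
                         stringsAsFactors = FALSE),
              as.data.frame(row, stringsAsFactors = FALSE))
  df
}

#' Extract the full metric battery from one gait trial
#'
#' Runs event detection on both shank gyros, derives the temporal,
#' symmetry and Poincare-variability metrics, and computes harmonic
#' ratio, multiscale entropy and RQA on each trunk-acceleration axis.
#'
#' @param trial A `gait_trial`.
#' @param child Optional one-row child record supplying clinical features
#'   and body length (`length_t24_cm`).
#' @param cfg A [complexity_config()].
#' @param thresholds An [event_thresholds()].
#' @return One-row metric `data.frame` (see [assemble_metric_vector()]).
#' @export
extract_trial_metrics <- function(trial, child = NULL,
                                  cfg = complexity_config(),
                                  thresholds = event_thresholds()) {
  stopifnot(inherits(trial, "gait_trial"))
  left <- detect_gait_events(trial$shank_gyro_left, trial$fs, thresholds, "left")
  right <- detect_gait_events(trial$shank_gyro_right, trial$fs, thresholds, "right")
  body_len <- if (!is.null(child) && is.finite(child$length_t24_cm %||% NA))
    child$length_t24_cm / 100 else NULL
  temporal <- withCallingHandlers(
    temporal_parameters(left, right, body_len),
    warning = function(w) invokeRestart("muffleWarning"))
  symm <- symmetry_indices(
    list(stride = temporal$stride_left, step = temporal$step_left),
    list(stride = temporal$stride_right, step = temporal$step_right))
  variability <- list(
    strideT = poincare(temporal$strideT_values),
    stepT = poincare(temporal$stepT_values),
    DS = poincare(temporal$DS_values))
  hr <- list(); mse <- list(); rq <- list()
  for (ax in c("v", "ml", "ap")) {
    acc <- trial$trunk_acc[, ax]
    hr[[paste0("HR_", ax)]] <-
      as.numeric(harmonic_ratio(acc, left$heel_strikes, ax, trial$fs, cfg))
    mse[[ax]] <- multiscale_entropy(acc, cfg)
    rq[[ax]] <- rqa(acc, cfg)
  }
  clinical <- if (is.null(child)) list() else {
    cl <- as.list(child[intersect(clinical_feature_names(), names(child))])
    cl
  }
  assemble_metric_vector(temporal, variability, hr, symm, mse, rq, clinical,
                         child_id = trial$child_id,
                         group = child$group %||% NA_character_,
                         risk = child$risk %||% NA_character_)
}

#' Extract metrics for a whole cohort
#'
#' Generates (or loads) one gait trial per child and extracts the metric
#' battery, returning the per-cohort metrics table consumed by the
#' analysis stage.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param base_params Base [gait_params()] shared by all children.
#' @param effects High-risk effect shifts ([default_effect_sizes()]).
#' @param master_seed Master seed; per-child trial seeds are derived by
#'   hashing `(master_seed, child_id)`.
#' @param cfg,thresholds Metric and event-detection configuration.
#' @param trials Optional named list of pre-generated `gait_trial`s keyed
#'   by `child_id` (used by the file-based pipeline); when `NULL`, trials
#'   are simulated on the fly.
#' @return `data.frame` with one metric row per child.
#' @export
cohort_metrics <- function(cohort, base_params = gait_params(),
                           effects = default_effect_sizes(),
                           master_seed = 1L,
                           cfg = complexity_config(),
                           thresholds = event_thresholds(),
                           trials = NULL) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    child <- cohort[i, ]
    trial <- if (!is.null(trials)) trials[[child$child_id]] else
      generate_gait_trial(child,
                          child_gait_params(child, base_params, effects,
                                            master_seed),
                          seed = derive_seed(master_seed,
                                             paste0("trial/", child$child_id)))
    extract_trial_metrics(trial, child, cfg, thresholds)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
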