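#' Default pipeline configuration
#'
#' The full configuration tree for a pipeline run: cohort composition,
#' gait-generator settings, event-detection thresholds, complexity
#' configuration and analysis settings, plus the master seed. The
#' configuration is strictly validated: unknown keys are errors. Its hash
#' is embedded in the metadata of every output file.
#'
#' @return Nested named list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    salt = "gaitwin",
    version = "0.1.0",
    cohort = list(n_preterm = 29L, n_fullterm = 17L, miss_rate_cog = 0.05),
    gait = list(mean_stride_s = 0.95, stride_sd_s = 0.045, asymmetry = 1.0,
                stance_frac = 0.62, noise_sd = 0.5, duration_s = 60,
                fs = 100),
    effects = default_effect_sizes(),
    thresholds = list(ms_threshold = 50, min_stride_gap_s = 0.4),
    complexity = list(m = 2L, r_frac = 0.2, rqa_dim = 5L, rqa_delay = 10L,
                      rqa_radius_frac = 0.2),
    analysis = list(models = c("logreg", "dtree", "rf", "xgb", "svm_linear"),
                    split = 0.75, cv_folds = 5L, n_iter = 20L,
                    imbalance = "weights", kmeans_runs = 30L,
                    perplexity = 10, embed = TRUE)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on
#' [default_config()] and rejects unknown keys at any nesting level.
#'
#' @param config Path to a YAML file, a list of overrides, or `NULL` for
#'   the defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  ov <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys <- function(ov, ref, path = "") {
    bad <- setdiff(names(ov), names(ref))
    if (length(bad))
      abort_gw(sprintf("unknown config key%s: %s",
                       if (length(bad) > 1) "s" else "",
                       paste0(path, bad, collapse = ", ")),
               "gaitwin_config_error")
    for (k in names(ov))
      if (is.list(ov[[k]]) && is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        check_keys(ov[[k]], ref[[k]], paste0(path, k, "."))
  }
  check_keys(ov, base)
  cfg <- modifyList(base, ov)
  if (cfg$cohort$n_preterm + cfg$cohort$n_fullterm < 1L)
    abort_gw("cohort has zero children", "gaitwin_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

cfg_gait_params <- function(cfg)
  do.call(gait_params, cfg$gait[setdiff(names(cfg$gait), character())])

cfg_complexity <- function(cfg) do.call(complexity_config, cfg$complexity)

cfg_thresholds <- function(cfg) do.call(event_thresholds, cfg$thresholds)

cfg_cohort_spec <- function(cfg)
  cohort_spec(n_preterm = cfg$cohort$n_preterm,
              n_fullterm = cfg$cohort$n_fullterm,
              miss_rate_cog = cfg$cohort$miss_rate_cog,
              effect_sizes = cfg$effects, seed = cfg$seed)

log_line <- function(dir, stage, status, elapsed = NA, detail = NULL) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                stage = stage, status = status, elapsed_s = elapsed,
                detail = detail)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"), "\n",
      file = file.path(dir, "run.log.jsonl"), append = TRUE, sep = "")
  message(sprintf("[gaitwin] %s: %s%s", stage, status,
                  if (is.finite(elapsed)) sprintf(" (%.1fs)", elapsed) else ""))
}

write_meta <- function(dir, cfg) {
  jsonlite::write_json(list(config = unclass(cfg),
                            config_hash = config_hash(unclass(cfg)),
                            seed = cfg$seed, version = cfg$version),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Pipeline stages
#'
#' `stage_simulate` writes the cohort CSV and per-child trial CSV/JSON
#' files; `stage_extract` reads them back and writes the metrics CSV;
#' `stage_twin` writes one twin JSON bundle per child plus the cohort
#' Turtle and knowledge-graph exports; `stage_analyze` runs clustering,
#' classification and attribution and writes their reports. All outputs
#' carry the configuration hash via `metadata.json`.
#'
#' @param cfg A `pipeline_config`.
#' @param dir Run directory.
#' @return Invisibly, the paths written.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(cfg, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg_cohort_spec(cfg))
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
  base <- cfg_gait_params(cfg)
  for (i in seq_len(nrow(cohort))) {
    child <- cohort[i, ]
    trial <- generate_gait_trial(
      child, child_gait_params(child, base, cfg$effects, cfg$seed),
      seed = derive_seed(cfg$seed, paste0("trial/", child$child_id)))
    write_trial_csv(trial,
                    file.path(dir, "trials", paste0(child$child_id, ".csv")),
                    file.path(dir, "trials", paste0(child$child_id, ".json")))
  }
  invisible(file.path(dir, "cohort.csv"))
}

#' @rdname pipeline_stages
#' @export
stage_extract <- function(cfg, dir) {
  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  trials <- lapply(stats::setNames(cohort$child_id, cohort$child_id),
                   function(id) {
    csv <- file.path(dir, "trials", paste0(id, ".csv"))
    if (!file.exists(csv))
      abort_gw(sprintf("trial file missing for %s", id),
               "gaitwin_missing_trial_error")
    read_trial_csv(csv, file.path(dir, "trials", paste0(id, ".json")))
  })
  metrics <- cohort_metrics(cohort, cfg_gait_params(cfg), cfg$effects,
                            cfg$seed, cfg_complexity(cfg),
                            cfg_thresholds(cfg), trials = trials)
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(file.path(dir, "metrics.csv"))
}

#' @rdname pipeline_stages
#' @export
stage_twin <- function(cfg, dir) {
  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  metrics <- read.csv(file.path(dir, "metrics.csv"), stringsAsFactors = FALSE)
  dir.create(file.path(dir, "twins"), showWarnings = FALSE)
  ch <- config_hash(unclass(cfg))
  docs <- lapply(seq_len(nrow(cohort)), function(i) {
    doc <- build_twin(cohort[i, ], metrics[i, ], timepoint = "T24",
                      salt = cfg$salt, cfg_hash = ch,
                      created = "1970-01-01T00:00:00Z")
    writeLines(to_fhir_json(doc),
               file.path(dir, "twins", paste0(doc$subject, ".json")))
    doc
  })
  writeLines(paste0(vapply(docs, to_rdf_turtle, character(1)),
                    collapse = "\n"),
             file.path(dir, "twins.ttl"))
  kg <- export_knowledge_graph(docs)
  write.csv(kg$edges, file.path(dir, "kg_edges.csv"), row.names = FALSE)
  writeLines(kg$turtle, file.path(dir, "kg.ttl"))
  invisible(file.path(dir, "twins"))
}

#' @rdname pipeline_stages
#' @export
stage_analyze <- function(cfg, dir) {
  metrics <- read.csv(file.path(dir, "metrics.csv"), stringsAsFactors = FALSE)
  ft <- build_feature_table(metrics)
  an <- cfg$analysis

  # clustering on the fully imputed + scaled table
  imp <- impute(ft$X, "mean")
  sc <- suppressWarnings(minmax_scale(imp))
  cl <- kmeans_repeated(sc$scaled, k = 2L, runs = an$kmeans_runs,
                        seed = derive_seed(cfg$seed, "cluster"))
  comp <- cluster_composition(cl, as.character(ft$y))
  jsonlite::write_json(
    list(importance = cl$importance, composition = comp,
         consensus = cl$consensus),
    file.path(dir, "cluster.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  if (isTRUE(an$embed) && nrow(sc$scaled) >= 3 * an$perplexity) {
    emb <- embed_2d(sc$scaled, seed = derive_seed(cfg$seed, "embed"),
                    perplexity = an$perplexity)
    write.csv(data.frame(child_id = ft$child_id, dim1 = emb$Y[, 1],
                         dim2 = emb$Y[, 2], risk = as.character(ft$y)),
              file.path(dir, "embedding.csv"), row.names = FALSE)
  }

  reports <- lapply(an$models, function(mn)
    train_and_evaluate(ft$X, ft$y, model = mn, split = an$split,
                       cv_folds = an$cv_folds, n_iter = an$n_iter,
                       imbalance = an$imbalance,
                       seed = derive_seed(cfg$seed, paste0("clf/", mn))))
  names(reports) <- an$models
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model, Acc = r$Acc, BA = r$BA,
               precision = r$precision, recall = r$recall, F1 = r$F1,
               AUC = r$AUC, MCC = r$MCC, cv_ba = r$cv_ba)))
  rownames(tab) <- NULL
  write.csv(tab, file.path(dir, "classification.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(reports, function(r)
    r[c("model", "TP", "FP", "FN", "TN", "Acc", "BA", "precision", "recall",
        "F1", "AUC", "MCC", "best_params", "cv_ba")]),
    file.path(dir, "classification.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  best <- reports[[which.max(vapply(reports, function(r) r$BA, numeric(1)))]]
  attr_tab <- feature_attribution(best, repeats = 10L,
                                  seed = derive_seed(cfg$seed, "attr"))
  write.csv(attr_tab, file.path(dir, "attribution.csv"), row.names = FALSE)
  invisible(file.path(dir, "classification.csv"))
}

#' Run the full pipeline
#'
#' Executes simulate, extract, twin and analyze in order inside `out_dir`,
#' logging per-stage timing to `run.log.jsonl` and embedding the
#' configuration hash and seed in `metadata.json`. On a stage failure the
#' partial outputs are preserved and a classed error names the failing
#' stage.
#'
#' @param config A config path/list/`pipeline_config` (see [load_config()]).
#' @param out_dir Run directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_meta(out_dir, cfg)
  stages <- list(simulate = stage_simulate, extract = stage_extract,
                 twin = stage_twin, analyze = stage_analyze)
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      stages[[nm]](cfg, out_dir)
      NULL
    }, error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (is.null(res)) {
      log_line(out_dir, nm, "ok", el)
    } else {
      log_line(out_dir, nm, "failed", el, conditionMessage(res))
      abort_gw(sprintf("stage '%s' failed: %s", nm, conditionMessage(res)),
               "gaitwin_stage_error")
    }
  }
  invisible(out_dir)
}

#' Generate the miniature fixture dataset used by the test-suite
#'
#' A deterministic 6-child mini-cohort (2 high-risk, one child with a
#' missing cognitive score) with 20-s trials, written in the same layout
#' as [stage_simulate()]. Regeneration with the pinned seed reproduces
#' the files byte for byte.
#'
#' @param out_dir Output directory.
#' @param seed Pinned seed (changing it changes the fixture).
#' @return The cohort `data.frame`, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 101L) {
  dir.create(file.path(out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  ga <- c(25, 27, 31, 34, 39, 40)
  bw <- c(760, 980, 1700, 2200, 3300, 3550)
  cohort <- data.frame(
    child_id = sprintf("child-%03d", 1:6),
    sex = c("F", "M", "F", "M", "F", "M"),
    ga_weeks = ga, twin = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    bw_g = bw,
    length_birth_cm = c(31, 33.5, 39, 43, 49.5, 50.5),
    length_t24_cm = c(83, 84.5, 85.5, 86, 87, 88),
    weight_t24_g = c(10900, 11300, 11800, 12100, 12400, 12600),
    walk_exp_weeks = c(34, 39, 45, 47, 52, 50),
    cog_score = c(88, NA, 98, 102, 108, 104),
    group = c(rep("preterm", 4), rep("fullterm", 2)),
    risk = NA_character_, stringsAsFactors = FALSE)
  cohort$risk <- assign_risk_label(cohort$ga_weeks, cohort$bw_g)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  base <- gait_params(duration_s = 20)
  for (i in seq_len(nrow(cohort))) {
    child <- cohort[i, ]
    trial <- generate_gait_trial(
      child, child_gait_params(child, base, default_effect_sizes(), seed),
      seed = derive_seed(seed, paste0("trial/", child$child_id)))
    write_trial_csv(trial,
                    file.path(out_dir, "trials", paste0(child$child_id, ".csv")),
                    file.path(out_dir, "trials", paste0(child$child_id, ".json")))
  }
  invisible(cohort)
}
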