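# Result tables in the published layout, run configuration, and end-to-end
# orchestration.

#' Result table across feature subsets
#'
#' One row per subset in the published column layout: `feature_set`, `n`,
#' mean confusion cells, TPR/FPR/accuracy with their SDs — all percentages
#' rounded half-up to 2 decimals — plus a `highlight` flag for rows at or
#' above the accuracy threshold.
#'
#' @param results Named list of [cv_result()]s, keyed by feature-subset name.
#' @param highlight_accuracy Accuracy threshold (percent) for flagging rows
#'   (default 65).
#' @return Data frame, one row per subset.
#' @export
report_table <- function(results, highlight_accuracy = 65) {
  cols <- c("feature_set", "n", "mean_tp", "mean_fn", "mean_fp", "mean_tn",
            "tpr", "sd_tpr", "fpr", "sd_fpr", "accuracy", "sd_accuracy",
            "highlight")
  if (!length(results)) {
    df <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
    df$feature_set <- character(); df$highlight <- logical()
    return(df[, cols])
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    n_feat <- if (!is.null(r$config$features) && !identical(r$config$features, "ttest_top3 (per-fold selection)"))
      length(r$config$features) else if (identical(r$config$subset, "ttest_top3")) 3L else NA_integer_
    data.frame(
      feature_set = nm, n = n_feat,
      mean_tp = round_half_up(r$mean_tp, 2), mean_fn = round_half_up(r$mean_fn, 2),
      mean_fp = round_half_up(r$mean_fp, 2), mean_tn = round_half_up(r$mean_tn, 2),
      tpr = round_half_up(r$tpr, 2), sd_tpr = round_half_up(r$sd_tpr, 2),
      fpr = round_half_up(r$fpr, 2), sd_fpr = round_half_up(r$sd_fpr, 2),
      accuracy = round_half_up(r$accuracy, 2),
      sd_accuracy = round_half_up(r$sd_accuracy, 2),
      highlight = round_half_up(r$accuracy, 2) >= highlight_accuracy,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resolve a pipeline configuration
#'
#' Merges user overrides (an R list or a YAML file) over the defaults:
#' synthetic-cohort settings ([synthetic_config()]), grid geometry
#' overrides, SVM and CV settings, and the feature-subset list. Every field
#' has a default; the fully resolved config (and its hash) is echoed into
#' every output.
#'
#' @param config `NULL` (defaults), a named list of overrides, or a path to
#'   a YAML file of overrides.
#' @return A `pipeline_config` list with elements `synthetic`, `geometry`,
#'   `svm`, `cv`, `subsets`, `highlight_accuracy`, `hash`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  known <- c("synthetic", "geometry", "svm", "cv", "subsets", "highlight_accuracy",
             "manifest", "data_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("pipeline_config: unknown field(s): ", paste(unknown, collapse = ", "))
  syn_args <- config$synthetic %||% list()
  if (!is.null(syn_args$tau_baseline_ps)) syn_args$tau_baseline_ps <- unlist(syn_args$tau_baseline_ps)
  resolved <- list(
    synthetic = do.call(synthetic_config, syn_args),
    geometry = modifyList(list(field_of_view_deg = 30, mm_per_degree = 0.3,
                               ring_diameters_mm = c(1, 3, 6), temporal_side = "left"),
                          config$geometry %||% list()),
    svm = do.call(svm_config, config$svm %||% list()),
    cv = do.call(cv_config, config$cv %||% list()),
    subsets = config$subsets %||% flio_subset_names(),
    highlight_accuracy = config$highlight_accuracy %||% 65,
    manifest = config$manifest, data_dir = config$data_dir)
  bad <- setdiff(resolved$subsets, flio_subset_names())
  if (length(bad))
    stop("pipeline_config: unknown feature subset(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(flio_subset_names(), collapse = ", "))
  resolved$hash <- rlang::hash(resolved[setdiff(names(resolved), "hash")])
  structure(resolved, class = "pipeline_config")
}

pipeline_log <- function(out_dir, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

#' Run the FLIO pipeline end to end
#'
#' Simulate (or load) a cohort, extract the ETDRS feature table, run the
#' repeated grouped CV for every configured feature subset and both
#' classification tasks, and write `features.csv`, one `result_*.json` per
#' subset/task, `report_smoker.csv` / `report_heavy.csv`, a t-test ranking
#' table, the resolved configuration and a stage-tagged log into `out_dir`.
#' Reruns with an identical configuration produce identical reports.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the feature table, per-task result lists
#'   and report data frames.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(config = unclass(cfg)),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  t0 <- Sys.time()
  if (!is.null(cfg$manifest)) {
    pipeline_log(out_dir, "load", sprintf("loading cohort from %s", cfg$manifest))
    cohort <- load_cohort(cfg$manifest, cfg$data_dir %||% dirname(cfg$manifest))
  } else {
    pipeline_log(out_dir, "simulate", sprintf(
      "generating synthetic cohort (seed %d, %d/%d/%d subjects)",
      cfg$synthetic$seed, cfg$synthetic$n_non_smokers, cfg$synthetic$n_light,
      cfg$synthetic$n_heavy))
    cohort <- generate_cohort(cfg$synthetic, modalities = "flio")$cohort
  }
  pipeline_log(out_dir, "extract", sprintf("%d FLIO samples", length(cohort$flio)))
  features <- extract_cohort_features(cohort)
  write_feature_table(features, file.path(out_dir, "features.csv"))
  ranking <- ttest_rank(features,
                        ifelse(features$label == "non_smoker", "non", "smoker"),
                        features = flio_subset_columns("tau_m"))
  write.csv(ranking, file.path(out_dir, "ttest_ranking.csv"), row.names = FALSE)

  all_results <- list()
  reports <- list()
  for (task in c("smoker", "heavy_smoker")) {
    cv <- modifyList(cfg$cv, list(positive_class = task))
    class(cv) <- "cv_config"
    results <- list()
    for (subset in cfg$subsets) {
      t1 <- Sys.time()
      res <- run_cv(features, subset, cv, cfg$svm)
      res$config$config_hash <- cfg$hash
      results[[subset]] <- res
      save_cv_result(res, file.path(out_dir, sprintf("result_%s_%s.json", task, subset)))
      pipeline_log(out_dir, "run-cv", sprintf(
        "%s / %s: accuracy %.2f%% +/- %.2f (%.1fs)", task, subset, res$accuracy,
        res$sd_accuracy, as.numeric(difftime(Sys.time(), t1, units = "secs"))))
    }
    rep_df <- report_table(results, cfg$highlight_accuracy)
    rep_df$config_hash <- cfg$hash
    write.csv(rep_df, file.path(out_dir, sprintf("report_%s.csv", task)),
              row.names = FALSE)
    all_results[[task]] <- results
    reports[[task]] <- rep_df
  }
  pipeline_log(out_dir, "done", sprintf(
    "total %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(features = features, results = all_results, reports = reports,
                 config = cfg))
}
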