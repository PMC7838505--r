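# End-to-end orchestration: simulate -> connectome -> topology -> selection ->
# classification, with deterministic stage-derived seeds, schema'd text
# artifacts, and a run record carrying config, timings and file digests.

#' Pipeline configuration
#'
#' Validates and freezes every tunable of a full run. Stage seeds are derived
#' deterministically from the master seed and the stage name, so stages rerun
#' in isolation reproduce their in-pipeline behavior.
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort_spec a [cohort_spec()] to simulate, or `NULL` to read an
#'   existing cohort from `cohort_dir`.
#' @param cohort_dir directory with a written cohort (used when
#'   `cohort_spec` is NULL).
#' @param feature_sets subset of `c("fc", "tf")`: FC edge features and/or
#'   sparsity-integrated topology features.
#' @param sparsities sparsity grid for the topology stage.
#' @param n_null null networks per sparsity.
#' @param ci_level,top_pct,n_repetitions,k_inner selection tunables (see
#'   [selection_config()]).
#' @param cv_folds outer CV folds.
#' @param ridge ridge penalty for the MLR.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort_spec = NULL, cohort_dir = NULL,
                            feature_sets = "fc",
                            sparsities = seq(0.01, 0.34, by = 0.01),
                            n_null = 20, ci_level = 0.996, top_pct = 0.05,
                            n_repetitions = 100, k_inner = 5, cv_folds = 10,
                            ridge = 1e-4, seed = 1L) {
  stopifnot(length(feature_sets) >= 1, all(feature_sets %in% c("fc", "tf")))
  if (is.null(cohort_spec) && is.null(cohort_dir))
    stop("either cohort_spec (simulate) or cohort_dir (read) is required")
  if (!is.null(cohort_spec)) stopifnot(inherits(cohort_spec, "cohort_spec"))
  # validates ci_level / top_pct ranges before any computation
  sel <- selection_config(ci_level = ci_level, top_pct = top_pct,
                          n_repetitions = n_repetitions, k_inner = k_inner,
                          seed = derive_seed(seed, "selection"))
  structure(list(out_dir = out_dir, cohort_spec = cohort_spec,
                 cohort_dir = cohort_dir, feature_sets = feature_sets,
                 sparsities = sparsities, n_null = n_null,
                 selection = sel, cv_folds = cv_folds, ridge = ridge,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), connectome, topology (optional), selection
#' and classification; writes all artifacts under `config$out_dir` and a
#' `run_record.json` with the config snapshot, package version, per-stage
#' wall time and md5 digests of every output. Reruns with the same config are
#' bit-identical.
#'
#' Artifacts: `cohort/` (time-series TSVs, manifest, ground truth),
#' `fc_features.csv`, `tf_features.csv` (when requested),
#' `selection_report.json`, `ranked_features.tsv`, `evaluation.json`,
#' `roc_points.csv`, `run_record.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `record`, `evaluation`, `frequency`,
#'   `predictive`, and the `feature_table` used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- tick("simulate", {
    if (!is.null(config$cohort_spec)) {
      co <- generate_cohort(config$cohort_spec)
      write_cohort(co, file.path(config$out_dir, "cohort"))
      co
    } else {
      read_cohort(config$cohort_dir)
    }
  })
  man <- cohort_manifest(cohort)

  fc_X <- tick("connectome", {
    X <- cohort_fc_features(cohort)
    write_feature_csv(X, man$id, file.path(config$out_dir, "fc_features.csv"))
    X
  })

  tf_X <- NULL
  if ("tf" %in% config$feature_sets) {
    tf_X <- tick("topology", {
      X <- cohort_topology_features(cohort, sparsities = config$sparsities,
                                    n_null = config$n_null,
                                    seed = derive_seed(config$seed, "topology"))
      write_feature_csv(X, man$id, file.path(config$out_dir, "tf_features.csv"))
      X
    })
  }

  feats <- if (identical(config$feature_sets, "tf")) tf_X else
    if (is.null(tf_X)) fc_X else cbind(fc_X, tf_X)
  ft <- cohort_feature_table(cohort, feats)

  sel_out <- tick("select", {
    freq <- repeated_selection(ft, config$selection)
    predictive <- pick_predictive(freq, config$selection$top_pct)
    ranked <- data.frame(feature_id = names(sort(freq$counts, decreasing = TRUE)),
                         count = sort(freq$counts, decreasing = TRUE),
                         row.names = NULL)
    utils::write.table(ranked[ranked$count > 0, ],
                       file.path(config$out_dir, "ranked_features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config = unclass(config$selection),
           total_draws = freq$total_draws,
           predictive = predictive,
           frequency = as.list(freq$counts[freq$counts > 0])),
      file.path(config$out_dir, "selection_report.json"),
      auto_unbox = TRUE, digits = NA)
    list(frequency = freq, predictive = predictive)
  })

  evaluation <- tick("classify", {
    ev <- outer_cv_evaluate(ft, config$selection, cv_folds = config$cv_folds,
                            seed = derive_seed(config$seed, "classification"),
                            ridge = config$ridge)
    jsonlite::write_json(
      list(train = list(fold_aucs = ev$train$fold_aucs,
                        mean = ev$train$mean, sd = ev$train$sd),
           validation = list(fold_aucs = ev$validation$fold_aucs,
                             mean = ev$validation$mean, sd = ev$validation$sd),
           selected = ev$selected),
      file.path(config$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA)
    roc_df <- do.call(rbind, lapply(seq_along(ev$validation$roc), function(f) {
      cbind(fold = f, ev$validation$roc[[f]])
    }))
    utils::write.csv(roc_df, file.path(config$out_dir, "roc_points.csv"),
                     row.names = FALSE)
    ev
  })

  artifacts <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "run_record.json"]
  digests <- tools::md5sum(artifacts)
  names(digests) <- substring(artifacts, nchar(config$out_dir) + 2L)
  record <- list(
    package_version = as.character(utils::packageVersion("contranet")),
    seed = config$seed,
    feature_sets = config$feature_sets,
    selection = unclass(config$selection),
    cv_folds = config$cv_folds,
    ridge = config$ridge,
    stage_seconds = as.list(timings),
    digests = as.list(digests))
  jsonlite::write_json(record, file.path(config$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(record = record, evaluation = evaluation,
                 frequency = sel_out$frequency,
                 predictive = sel_out$predictive,
                 feature_table = ft))
}

#' Sweep the selection hyperparameter grid
#'
#' Reruns selection + classification for every combination of one-sided CI
#' level and top-percent threshold (the grid the screening procedure is
#' designed around: CI 95 to 99.9%, top 1 to 20%) on a fixed cohort, and
#' tabulates the validation AUC. The best cell is flagged.
#'
#' @param config a [pipeline_config()] (the cohort is built or read once).
#' @param ci_levels vector of one-sided CI levels.
#' @param top_pcts vector of top fractions.
#' @return data.frame with columns ci_level, top_pct, auc_mean, auc_sd,
#'   train_auc_mean, best.
#' @export
sweep_hyperparams <- function(config, ci_levels, top_pcts) {
  stopifnot(inherits(config, "pipeline_config"),
            length(ci_levels) >= 1, length(top_pcts) >= 1)
  cohort <- if (!is.null(config$cohort_spec)) generate_cohort(config$cohort_spec)
    else read_cohort(config$cohort_dir)
  feats <- list()
  if ("fc" %in% config$feature_sets) feats$fc <- cohort_fc_features(cohort)
  if ("tf" %in% config$feature_sets)
    feats$tf <- cohort_topology_features(cohort, sparsities = config$sparsities,
                                         n_null = config$n_null,
                                         seed = derive_seed(config$seed, "topology"))
  ft <- cohort_feature_table(cohort, do.call(cbind, feats))
  grid <- expand.grid(ci_level = ci_levels, top_pct = top_pcts,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- selection_config(ci_level = grid$ci_level[g],
                            top_pct = grid$top_pct[g],
                            n_repetitions = config$selection$n_repetitions,
                            k_inner = config$selection$k_inner,
                            seed = config$selection$seed)
    ev <- outer_cv_evaluate(ft, cfg, cv_folds = config$cv_folds,
                            seed = derive_seed(config$seed, "classification"),
                            ridge = config$ridge)
    c(auc_mean = ev$validation$mean, auc_sd = ev$validation$sd,
      train_auc_mean = ev$train$mean)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$best <- seq_len(nrow(out)) == which.max(out$auc_mean)
  out
}
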