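# Cohort and feature-table file I/O. All formats are plain text: one TSV per
# subject (nodes x timepoints, no header), a manifest CSV, a ground-truth JSON,
# and cohort-level feature CSVs.

#' Write a cohort to disk
#'
#' Writes one tab-separated time-series file per subject (nodes x timepoints,
#' no header), a manifest CSV (id, group, hemisphere, age, sex,
#' timeseries_path) and a ground-truth JSON (planted edges, effect size, seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$timeseries_path <- paste0("ts_", man$id, ".tsv")
  for (s in cohort$subjects) {
    utils::write.table(s$timeseries, file.path(dir, paste0("ts_", s$id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(planted_edges = unname(apply(gt$planted_edges, 1, as.integer,
                                      simplify = FALSE)),
         effect_size = gt$effect_size, seed = gt$seed,
         n_nodes = cohort$spec$n_nodes,
         tr_seconds = cohort$spec$tr_seconds),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and time-series TSVs.
#' @return object of class `cohort` (ground truth restored from JSON when
#'   present; covariance matrices are not stored on disk).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(man)), function(s) {
    ts <- as.matrix(utils::read.table(file.path(dir, man$timeseries_path[s]),
                                      sep = "\t", header = FALSE))
    dimnames(ts) <- NULL
    list(id = man$id[s], group = man$group[s], hemisphere = man$hemisphere[s],
         age = man$age[s], sex = man$sex[s], timeseries = ts)
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- NULL
  tr <- 2.0
  n_nodes <- nrow(subjects[[1L]]$timeseries)
  if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    pe <- if (length(g$planted_edges)) {
      matrix(as.integer(unlist(g$planted_edges)), ncol = 2L, byrow = TRUE,
             dimnames = list(NULL, c("i", "j")))
    } else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
    gt <- list(planted_edges = pe, effect_size = g$effect_size, seed = g$seed)
    tr <- g$tr_seconds %||% tr
    n_nodes <- g$n_nodes %||% n_nodes
  }
  structure(list(subjects = subjects,
                 spec = list(n_nodes = n_nodes,
                             n_timepoints = ncol(subjects[[1L]]$timeseries),
                             tr_seconds = tr,
                             hemisphere = man$hemisphere[1L]),
                 ground_truth = gt),
            class = "cohort")
}

#' Write a per-subject feature matrix as CSV
#'
#' One row per subject: subject_id column followed by one column per feature.
#'
#' @param X numeric matrix (subjects x features) with column names.
#' @param subject_ids character vector, one per row.
#' @param path output file.
#' @export
write_feature_csv <- function(X, subject_ids, path) {
  stopifnot(nrow(X) == length(subject_ids), !is.null(colnames(X)))
  df <- data.frame(subject_id = subject_ids, X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path file path.
#' @return list with `X` (matrix) and `subject_ids`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- NULL
  list(X = X, subject_ids = df[[1L]])
}
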