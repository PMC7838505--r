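# Repeated inner-CV ROC/AUC feature screening.
#
# Three steps: (1) per-feature ROC/AUC on the train-train portion of each
# inner stratified fold; (2) candidate selection by thresholding the fitted
# normal distribution of the AUC vector with a one-sided confidence level;
# (3) repetition with re-randomized folds, frequency counting, and extraction
# of the top-percent most frequently selected features.

#' Feature table container
#'
#' Light validated container for a subjects x features matrix with binary
#' class labels (LGG = 0, HGG = 1) and optional age covariate.
#'
#' @param X numeric matrix (subjects x features) with unique column names.
#' @param labels vector coercible to 0/1 (or a factor/character with levels
#'   LGG/HGG).
#' @param age optional numeric vector of ages.
#' @param subject_ids optional character ids (default from rownames).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(X, labels, age = NULL, subject_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("feature ids must be unique")
  if (!all(is.finite(X))) stop("feature matrix contains non-finite entries")
  y <- normalize_labels(labels)
  if (length(y) != nrow(X)) stop("labels length must match rows of X")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!is.null(age)) {
    stopifnot(length(age) == nrow(X), all(is.finite(age)))
  }
  structure(list(X = X, y = y, age = age,
                 feature_ids = colnames(X),
                 subject_ids = subject_ids %||% rownames(X) %||%
                   paste0("s", seq_len(nrow(X)))),
            class = "feature_table")
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("LGG", "HGG")))
      stop("character labels must be LGG/HGG")
    return(as.integer(labels == "HGG"))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("numeric labels must be 0/1")
  y
}

#' Build a feature table from a cohort and a feature matrix
#'
#' @param cohort a `cohort` object.
#' @param X feature matrix with one row per subject, in cohort order (e.g.
#'   from [cohort_fc_features()] or [cohort_topology_features()]).
#' @return a [feature_table()] with labels and age from the manifest.
#' @export
cohort_feature_table <- function(cohort, X) {
  man <- cohort_manifest(cohort)
  feature_table(X, labels = man$group, age = man$age, subject_ids = man$id)
}

#' Per-feature ROC AUC (Mann-Whitney)
#'
#' Rank-based AUC of a single feature for discriminating the two classes
#' (ties contribute 1/2). By default the value is direction-folded to
#' `max(a, 1 - a)` so anti-correlated features score symmetrically; set
#' `fold = FALSE` for the raw one-sided value `P(x_1 > x_0)`.
#'
#' @param values numeric feature values.
#' @param labels 0/1 class labels (both classes present).
#' @param fold fold to `max(a, 1 - a)` (default TRUE).
#' @return AUC in `[0.5, 1]` (folded) or `[0, 1]` (raw).
#' @export
feature_auc <- function(values, labels, fold = TRUE) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- length(y) - n1
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  a <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  if (fold) max(a, 1 - a) else a
}

# vectorized per-column AUC: a single rank() call over the column-offset
# flattened matrix (columns are separated by a constant larger than the data
# range, so global ranks decompose into within-column ranks)
col_aucs <- function(X, y, fold = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  v <- as.vector(X)
  sep <- 2 * max(abs(v)) + 1
  off <- rep(seq_len(p) - 1L, each = n)
  r <- rank(v + off * sep, ties.method = "average") - off * n
  R <- matrix(r, n, p)
  a <- (.colSums(R[y == 1L, , drop = FALSE], n1, p) - n1 * (n1 + 1) / 2) /
    (n0 * n1)
  if (fold) pmax(a, 1 - a) else a
}

#' One-sided AUC threshold from a fitted normal
#'
#' Fits a normal distribution to the vector of per-feature AUCs by the sample
#' mean and SD (n-1 denominator) and returns the one-sided confidence bound
#' `mean + z(ci) * sd`. Zero spread degenerates to the mean (flagged).
#'
#' @param aucs numeric vector of AUC values (length >= 2).
#' @param ci_level one-sided confidence level, e.g. 0.996.
#' @return threshold scalar; attribute `degenerate` when sd was zero.
#' @export
auc_threshold <- function(aucs, ci_level) {
  stopifnot(length(aucs) >= 2, ci_level > 0, ci_level < 1)
  s <- stats::sd(aucs)
  if (s == 0) {
    return(structure(mean(aucs), degenerate = TRUE))
  }
  mean(aucs) + stats::qnorm(ci_level) * s
}

#' Candidate features from one train-train subset
#'
#' Computes every feature's raw (one-sided) AUC on the given subset and keeps
#' the features whose AUC exceeds the fitted-normal one-sided bound of the
#' full AUC vector — i.e. features with unusually high AUC relative to the
#' cohort-wide AUC distribution. Under a pure-noise table the expected
#' candidate fraction is `1 - ci_level`.
#'
#' @param ft a [feature_table()] (the train-train subset).
#' @param ci_level one-sided confidence level.
#' @return character vector of candidate feature ids.
#' @export
candidates_one_fold <- function(ft, ci_level) {
  idx <- candidate_idx(ft$X, ft$y, ci_level)
  ft$feature_ids[idx]
}

candidate_idx <- function(X, y, ci_level) {
  a <- col_aucs(X, y, fold = FALSE)
  which(a > auc_threshold(a, ci_level))
}

#' Selection configuration
#'
#' @param ci_level one-sided confidence level in `[0.95, 0.999]`.
#' @param top_pct top fraction of candidate frequencies kept, in
#'   `[0.01, 0.20]`.
#' @param n_repetitions inner-CV repetitions (default 100).
#' @param k_inner inner folds (default 5).
#' @param seed integer seed.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(ci_level = 0.996, top_pct = 0.05,
                             n_repetitions = 100, k_inner = 5, seed = 1L) {
  if (!(ci_level >= 0.95 && ci_level <= 0.999))
    stop("ci_level must lie in [0.95, 0.999]")
  if (!(top_pct >= 0.01 && top_pct <= 0.20))
    stop("top_pct must lie in [0.01, 0.20]")
  stopifnot(n_repetitions >= 1, k_inner >= 2)
  structure(list(ci_level = ci_level, top_pct = top_pct,
                 n_repetitions = as.integer(n_repetitions),
                 k_inner = as.integer(k_inner), seed = as.integer(seed)),
            class = "selection_config")
}

#' Stratified fold assignment
#'
#' Random fold labels 1..k, stratified within class so every fold keeps the
#' class balance (and every train-train subset retains both classes for
#' classes of size >= 2).
#'
#' @param y 0/1 class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < 2L)
        stop("class ", cl, " too small for stratified folds")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Repeated inner-CV candidate selection with frequency counting
#'
#' For each of `n_repetitions` repetitions, draws a fresh seeded stratified
#' `k_inner`-fold partition of the training table; for each fold the
#' train-train portion (all other folds) is screened with
#' [candidates_one_fold()]. Each feature's selection count over all
#' `n_repetitions * k_inner` draws is recorded.
#'
#' @param ft a [feature_table()] (the training data).
#' @param cfg a [selection_config()].
#' @return object of class `frequency_table`: list with named integer
#'   `counts` and `total_draws`.
#' @export
repeated_selection <- function(ft, cfg) {
  stopifnot(inherits(ft, "feature_table"), inherits(cfg, "selection_config"))
  p <- ncol(ft$X)
  counts <- integer(p)
  for (r in seq_len(cfg$n_repetitions)) {
    fold <- stratified_folds(ft$y, cfg$k_inner,
                             seed = derive_seed(cfg$seed, sprintf("rep_%04d", r)))
    for (f in seq_len(cfg$k_inner)) {
      tt <- fold != f
      idx <- candidate_idx(ft$X[tt, , drop = FALSE], ft$y[tt], cfg$ci_level)
      counts[idx] <- counts[idx] + 1L
    }
  }
  names(counts) <- ft$feature_ids
  total <- cfg$n_repetitions * cfg$k_inner
  stopifnot(all(counts <= total))
  structure(list(counts = counts, total_draws = total),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf("<frequency_table> %d features, %d with nonzero count over %d draws\n",
              length(x$counts), nz, x$total_draws))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  print(utils::head(top, 10))
  invisible(x)
}

#' Extract the predictive features from a frequency table
#'
#' The `ceil(top_pct * n)` features with the highest selection counts, ties
#' broken by the canonical feature order; features never selected (zero
#' count) are excluded even when inside the top fraction. By default `n` is
#' the total feature count; `of = "candidates"` restricts the base to the
#' candidate pool (features with nonzero frequency), which yields much
#' smaller predictive sets when a few features dominate the screening.
#'
#' @param freq a [repeated_selection()] result.
#' @param top_pct fraction of features to keep.
#' @param of base of the fraction: `"all"` features (default) or
#'   `"candidates"` only.
#' @return character vector of predictive feature ids, ordered by
#'   decreasing count.
#' @export
pick_predictive <- function(freq, top_pct, of = c("all", "candidates")) {
  stopifnot(inherits(freq, "frequency_table"), top_pct > 0, top_pct <= 1)
  of <- match.arg(of)
  counts <- freq$counts
  if (!length(counts)) stop("frequency table is empty")
  base <- if (of == "all") length(counts) else sum(counts > 0)
  if (base == 0L) return(character(0))
  m <- ceiling(top_pct * base)
  ord <- order(-counts, seq_along(counts))
  top <- ord[seq_len(min(m, length(counts)))]
  top <- top[counts[top] > 0]
  names(counts)[top]
}
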