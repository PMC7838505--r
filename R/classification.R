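# SMOTE-balanced ridge-penalized multivariate logistic regression with
# stratified outer cross-validation and cross-hemisphere validation.
#
# Selection and SMOTE run strictly inside each outer training fold; held-out
# data never touch screening, oversampling or standardization.

#' SMOTE minority oversampling
#'
#' Generates synthetic minority-class points `x_new = x_i + u * (x_nn - x_i)`
#' with `u ~ Uniform(0, 1)` and `x_nn` one of the `k_neighbors` nearest
#' minority neighbors (Euclidean), until both classes have exactly the
#' majority count. Originals are preserved unchanged. If the minority class
#' has fewer than `k_neighbors + 1` members, k is reduced to minority size
#' minus one (with a message).
#'
#' @param X numeric matrix (subjects x features).
#' @param y 0/1 class labels.
#' @param k_neighbors neighbors considered per base point (default 5).
#' @param seed integer seed.
#' @return list with balanced `X` and `y` (originals first, synthetic rows
#'   appended).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- normalize_labels(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (tab[1L] == tab[2L]) return(list(X = X, y = y))
  min_lab <- as.integer(names(which.min(tab)))
  n_min <- min(tab)
  n_syn <- abs(tab[1L] - tab[2L])
  if (n_min < 2L) stop("minority class of 1 cannot be oversampled")
  k <- min(k_neighbors, n_min - 1L)
  if (k < k_neighbors)
    message("SMOTE: k_neighbors reduced to ", k, " (minority size ", n_min, ")")
  Xm <- X[y == min_lab, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  nn <- matrix(apply(D, 1L, function(r) order(r)[2:(k + 1L)]), nrow = k)
  draws <- withr::with_seed(as.integer(seed), {
    list(base = rep_len(seq_len(n_min), n_syn),
         pick = sample.int(k, n_syn, replace = TRUE),
         u = stats::runif(n_syn))
  })
  nb <- nn[cbind(draws$pick, draws$base)]
  syn <- Xm[draws$base, , drop = FALSE] +
    (Xm[nb, , drop = FALSE] - Xm[draws$base, , drop = FALSE]) * draws$u
  rownames(syn) <- NULL
  list(X = rbind(X, syn), y = c(y, rep(min_lab, n_syn)))
}

#' Fit a ridge-penalized multivariate logistic regression
#'
#' Features are z-scored internally (parameters learned on the supplied
#' training data and frozen in the model, so fitted models transport to other
#' cohorts). Coefficients are maximum penalized likelihood via damped
#' Newton/IRLS, with a small ridge on the slopes (not the intercept) for
#' stability on separable SMOTE-balanced data. `ridge = 0` reproduces the
#' ordinary ML fit when it exists.
#'
#' @param X numeric matrix (subjects x features) with column names.
#' @param y 0/1 class labels (>= 2 per class).
#' @param ridge ridge penalty on standardized slopes (default 1e-4).
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the penalized gradient norm.
#' @return object of class `mlr_model` with elements `coefficients`
#'   (intercept first), `feature_ids`, `center`, `scale`, `converged`.
#' @export
fit_mlr <- function(X, y, ridge = 1e-4, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- normalize_labels(y)
  stopifnot(sum(y == 0L) >= 2, sum(y == 1L) >= 2, ridge >= 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  Xs <- scale(X, center = mu, scale = sdv)
  n <- nrow(Xs)
  p <- ncol(Xs)
  design <- cbind(1, Xs)
  pen <- c(0, rep(ridge, p))
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(design %*% b)
    # numerically stable -log-likelihood: log(1+e^eta) = max(eta,0) + log1p(e^-|eta|)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) + sum(pen * b^2) / 2
  }
  cur <- obj(beta)
  converged <- FALSE
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    pr <- stats::plogis(eta)
    grad <- drop(crossprod(design, y - pr)) - pen * beta
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol * n) {
      converged <- TRUE
      break
    }
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(design * w, design) + diag(pen, p + 1L)
    step <- solve(H, grad)
    # damped Newton: halve until the penalized deviance does not increase
    lam <- 1
    repeat {
      cand <- beta + lam * step
      val <- obj(cand)
      if (val <= cur + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    cur <- val
  }
  if (!converged)
    stop(sprintf("IRLS did not converge in %d iterations (gradient norm %.3e)",
                 max_iter, grad_norm))
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = beta, feature_ids = colnames(X),
                 center = mu, scale = sdv, ridge = ridge,
                 converged = converged, iterations = it),
            class = "mlr_model")
}

#' Predict class probabilities from an MLR model
#'
#' @param object an `mlr_model`.
#' @param newdata numeric matrix containing (at least) the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of P(HGG) probabilities.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing))
    stop("newdata is missing model feature(s): ",
         paste(missing, collapse = ", "))
  Xs <- scale(newdata[, object$feature_ids, drop = FALSE],
              center = object$center, scale = object$scale)
  eta <- drop(cbind(1, Xs) %*% object$coefficients)
  stats::plogis(eta)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores; the AUC equals the tie-corrected
#' Mann-Whitney statistic exactly.
#'
#' @param scores numeric classifier scores (larger = more HGG-like).
#' @param labels 0/1 class labels (both present).
#' @return list with `points` (data.frame of fpr, tpr, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- length(y) - n1
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last <- which(!duplicated(ss, fromLast = TRUE))  # one point per threshold
  pts <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  list(points = pts, auc = auc)
}

new_evaluation_result <- function(fold_aucs, roc, context) {
  structure(list(fold_aucs = fold_aucs,
                 mean = mean(fold_aucs),
                 sd = stats::sd(fold_aucs),
                 roc = roc, context = context),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result:%s> AUC %.3f +/- %.3f over %d folds\n",
              x$context, x$mean, x$sd, length(x$fold_aucs)))
  invisible(x)
}

#' Outer cross-validated selection + classification
#'
#' Stratified `cv_folds`-fold outer CV. Within each fold the training portion
#' alone is screened with [repeated_selection()] / [pick_predictive()]; the
#' selected features (plus age, force-included by default) are SMOTE-balanced,
#' an MLR is fitted, and ROC/AUC is measured on the (original, un-augmented)
#' training portion and on the held-out portion. Fold models are returned for
#' cross-hemisphere validation.
#'
#' @param ft a [feature_table()] with age when `include_age = TRUE`.
#' @param cfg a [selection_config()].
#' @param cv_folds outer folds (default 10).
#' @param seed integer seed for folds, selection and SMOTE.
#' @param ridge ridge penalty for [fit_mlr()].
#' @param k_smote SMOTE neighbor count.
#' @param include_age force-include age as a model feature.
#' @return list with `train` and `validation` (class `evaluation_result`),
#'   `models` (per-fold `mlr_model`s), and `selected` (per-fold predictive
#'   feature ids).
#' @export
outer_cv_evaluate <- function(ft, cfg, cv_folds = 10, seed = 1L,
                              ridge = 1e-4, k_smote = 5,
                              include_age = TRUE) {
  stopifnot(inherits(ft, "feature_table"), inherits(cfg, "selection_config"),
            cv_folds >= 2)
  if (include_age && is.null(ft$age))
    stop("feature table has no age but include_age = TRUE")
  fold <- stratified_folds(ft$y, cv_folds, seed = derive_seed(seed, "outer_cv"))
  auc_tr <- numeric(cv_folds)
  auc_val <- numeric(cv_folds)
  roc_tr <- vector("list", cv_folds)
  roc_val <- vector("list", cv_folds)
  models <- vector("list", cv_folds)
  selected <- vector("list", cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    ftr <- feature_table(ft$X[tr, , drop = FALSE], ft$y[tr],
                         age = ft$age[tr],
                         subject_ids = ft$subject_ids[tr])
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(seed, sprintf("selection_fold_%02d", f))
    freq <- repeated_selection(ftr, cfg_f)
    sel <- pick_predictive(freq, cfg$top_pct)
    selected[[f]] <- sel
    Xf <- ftr$X[, sel, drop = FALSE]
    if (include_age) Xf <- cbind(Xf, age = ftr$age)
    if (ncol(Xf) == 0L)
      stop(sprintf("fold %d: no features selected and age excluded", f))
    sm <- smote_oversample(Xf, ftr$y, k_neighbors = k_smote,
                           seed = derive_seed(seed, sprintf("smote_%02d", f)))
    model <- fit_mlr(sm$X, sm$y, ridge = ridge)
    models[[f]] <- model
    Xall <- ft$X[, sel, drop = FALSE]
    if (include_age) Xall <- cbind(Xall, age = ft$age)
    scores_tr <- predict(model, Xall[tr, , drop = FALSE])
    scores_val <- predict(model, Xall[!tr, , drop = FALSE])
    rt <- roc_auc(scores_tr, ft$y[tr])
    rv <- roc_auc(scores_val, ft$y[!tr])
    auc_tr[f] <- rt$auc
    auc_val[f] <- rv$auc
    roc_tr[[f]] <- rt$points
    roc_val[[f]] <- rv$points
  }
  list(train = new_evaluation_result(auc_tr, roc_tr, "train"),
       validation = new_evaluation_result(auc_val, roc_val, "validation"),
       models = models, selected = selected, fold = fold)
}

#' Validate fold models on the other hemisphere group
#'
#' Scores every fold model on the entire other-group feature table and
#' returns the AUC distribution. A hemisphere-specific signal shows up as a
#' cross-group mean AUC below the same-group validation mean.
#'
#' @param models list of `mlr_model`s (e.g. from [outer_cv_evaluate()]).
#' @param other_ft [feature_table()] of the other group, containing every
#'   model feature (plus age when the models use it).
#' @return `evaluation_result` with context `other_hemisphere`.
#' @export
cross_hemisphere_validate <- function(models, other_ft) {
  stopifnot(inherits(other_ft, "feature_table"), length(models) >= 1)
  Xo <- other_ft$X
  if (!is.null(other_ft$age)) Xo <- cbind(Xo, age = other_ft$age)
  aucs <- numeric(length(models))
  rocs <- vector("list", length(models))
  for (m in seq_along(models)) {
    sc <- predict(models[[m]], Xo)
    r <- roc_auc(sc, other_ft$y)
    aucs[m] <- r$auc
    rocs[[m]] <- r$points
  }
  new_evaluation_result(aucs, rocs, "other_hemisphere")
}

#' Compare two AUC distributions by t-test
#'
#' Two-tailed Student t-test: paired, or two-sample with pooled variance.
#' Degenerate zero-variance inputs with equal means return `t = 0, p = 1`.
#'
#' @param a,b numeric AUC vectors (equal length when `paired`).
#' @param paired paired test (default FALSE).
#' @return list with `t`, `p`, `df`.
#' @export
compare_auc_distributions <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) stopifnot(length(a) == length(b))
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1, df = if (paired) length(a) - 1
                  else length(a) + length(b) - 2))
    d <- mean(a) - mean(b)
    return(list(t = sign(d) * Inf, p = 0,
                df = if (paired) length(a) - 1 else length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (step-up, capped at 1).
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
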