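test_that("SMOTE balances classes exactly and interpolates the minority", {
  withr::with_seed(111, {
    X <- matrix(rnorm(46 * 4), 46, 4)
    y <- c(rep(1L, 14), rep(0L, 32))  # right-hemisphere class sizes
  })
  sm <- smote_oversample(X, y, k_neighbors = 5, seed = 2)
  expect_equal(as.integer(table(sm$y)), c(32L, 32L))
  # originals preserved unchanged, synthetic rows appended
  expect_identical(sm$X[1:46, ], X)
  # synthetic rows lie in the per-coordinate minority bounding box
  syn <- sm$X[47:nrow(sm$X), ]
  Xm <- X[y == 1L, ]
  for (j in 1:4) {
    expect_gte(min(syn[, j]), min(Xm[, j]) - 1e-12)
    expect_lte(max(syn[, j]), max(Xm[, j]) + 1e-12)
  }
  expect_identical(sm, smote_oversample(X, y, k_neighbors = 5, seed = 2))

  # already balanced: identity
  yb <- rep(c(0L, 1L), 10)
  Xb <- matrix(rnorm(40), 20, 2)
  expect_identical(smote_oversample(Xb, yb, seed = 1)$X, Xb)

  # collinear minority stays on its segment
  Xc <- rbind(cbind(seq(0, 1, length.out = 5), 2 * seq(0, 1, length.out = 5)),
              matrix(rnorm(24, 10), 12, 2))
  yc <- c(rep(1L, 5), rep(0L, 12))
  smc <- smote_oversample(Xc, yc, k_neighbors = 3, seed = 3)
  sync <- smc$X[18:nrow(smc$X), ]
  expect_lt(max(abs(sync[, 2] - 2 * sync[, 1])), 1e-12)

  expect_error(smote_oversample(Xc, c(1L, rep(0L, 16)), seed = 1),
               "minority class of 1")
})

test_that("ridge logistic regression matches glm and is monotone", {
  # 1-D perfectly ordered data: probabilities strictly increasing
  X <- matrix(seq(-2, 2, length.out = 20), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- as.integer(seq_len(20) > 10)
  fit <- fit_mlr(X, y, ridge = 1e-4)
  pr <- predict(fit, X)
  # strict monotonicity up to plogis saturation at the extremes
  expect_true(all(diff(pr) >= 0))
  expect_gt(pr[20] - pr[1], 0.9)
  expect_true(all(diff(pr[8:13]) > 0))

  # non-separable fixture at ridge = 0: equals glm's IRLS solution
  withr::with_seed(112, {
    X3 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    eta <- 0.8 * X3[, 1] - 0.5 * X3[, 3]
    y3 <- rbinom(20, 1, plogis(eta))
  })
  if (length(unique(y3)) == 1L) y3[1] <- 1L - y3[1]
  fit0 <- fit_mlr(X3, y3, ridge = 0)
  ref <- glm(y3 ~ scale(X3), family = binomial)
  expect_equal(unname(predict(fit0, X3)),
               unname(fitted(ref)), tolerance = 1e-6)

  # null data: slopes within 3 Wald SEs of zero
  withr::with_seed(113, {
    Xn <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    yn <- rbinom(200, 1, 0.5)
  })
  fitn <- fit_mlr(Xn, yn, ridge = 0)
  refn <- summary(glm(yn ~ scale(Xn), family = binomial))
  expect_true(all(abs(fitn$coefficients[-1]) <=
                  3 * refn$coefficients[-1, "Std. Error"]))

  expect_error(fit_mlr(cbind(x = rep(1, 10)), rep(c(0L, 1L), 5)),
               "zero-variance")
})

test_that("ROC/AUC equals the tie-corrected Mann-Whitney statistic", {
  # perfect and reversed rankings
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0.0)
  # hand-enumerated tie case: pairs (1 + 0.5 + 1 + 1)/4
  expect_equal(roc_auc(c(0.2, 0.4, 0.4, 0.9), c(0, 0, 1, 1))$auc, 0.875)

  # exhaustive pairwise-count oracle on many random fixtures
  for (s in 1:300) {
    withr::with_seed(5000 + s, {
      n <- sample(6:20, 1)
      sc <- round(rnorm(n), sample(0:2, 1))  # ties at coarse rounding
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    })
    pairs <- outer(sc[y == 1], sc[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, y)$auc, mean(pairs), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("t-test comparison and FDR adjustment match hand formulas", {
  expect_equal(compare_auc_distributions(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
               list(t = 0, p = 1, df = 2))
  expect_equal(compare_auc_distributions(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_auc_distributions(c(1, 2, 3), c(1, 2, 3))$p, 1)

  a <- c(0.9, 0.85, 0.88)
  b <- c(0.6, 0.62, 0.58)
  got <- compare_auc_distributions(a, b)
  # pooled-variance Student t, computed from first principles
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_hand, tolerance = 1e-6)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-6)

  # degenerate zero-variance inputs
  expect_equal(compare_auc_distributions(c(1, 1), c(1, 1))$p, 1)
  expect_equal(compare_auc_distributions(c(2, 2), c(1, 1))$p, 0)

  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # step-up formula oracle: cummin of sorted p * m / rank
  withr::with_seed(121, p <- runif(20))
  o <- order(p, decreasing = TRUE)
  hand <- pmin(1, cummin(p[o] * 20 / (20:1)))[order(o)]
  expect_equal(fdr_adjust(p), hand, tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("outer CV evaluates leak-free and rewards real signal", {
  # a small planted cohort: validation beats chance, train beats validation
  withr::with_seed(131, {
    n <- 60
    y <- rep(c(0L, 1L), each = 30)
    X <- matrix(rnorm(n * 300), n, 300)
    X[, 1:5] <- X[, 1:5] + y %o% rep(1.2, 5)
    colnames(X) <- paste0("f", 1:300)
    age <- rnorm(n, 45, 10)
  })
  ft <- feature_table(X, y, age = age)
  cfg <- selection_config(ci_level = 0.99, top_pct = 0.03,
                          n_repetitions = 5, k_inner = 5, seed = 3)
  ev <- outer_cv_evaluate(ft, cfg, cv_folds = 5, seed = 17)
  expect_gt(ev$validation$mean, 0.75)
  expect_gte(ev$train$mean, ev$validation$mean)
  expect_equal(ev$validation$sd, sd(ev$validation$fold_aucs), tolerance = 1e-12)
  expect_length(ev$models, 5)
  # determinism
  ev2 <- outer_cv_evaluate(ft, cfg, cv_folds = 5, seed = 17)
  expect_identical(ev$validation$fold_aucs, ev2$validation$fold_aucs)

  # scoring each fold model on its own held-out rows reproduces the
  # validation AUCs (consistency of cross-group scoring machinery)
  for (f in 1:5) {
    held <- ev$fold == f
    sub <- feature_table(ft$X[held, , drop = FALSE], ft$y[held],
                         age = ft$age[held])
    cx <- cross_hemisphere_validate(ev$models[f], sub)
    expect_equal(cx$fold_aucs, ev$validation$fold_aucs[f], tolerance = 1e-12)
  }

  # permuted labels after the fact: no transportable signal
  withr::with_seed(132, yperm <- sample(y))
  ftp <- feature_table(X, yperm, age = age)
  evp <- outer_cv_evaluate(ftp, cfg, cv_folds = 5, seed = 18)
  expect_gt(evp$validation$mean, 0.25)
  expect_lt(evp$validation$mean, 0.75)

  # missing model feature is named
  ft2 <- feature_table(X[, 10:300], y, age = age)
  expect_error(cross_hemisphere_validate(ev$models, ft2), "missing")
})
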