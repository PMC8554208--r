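# Confusion counts, metric formulas, ROC/AUC, cross-validation harness.

test_that("confusion counts are exact and symmetric under label flips", {
  expect_identical(unclass(confusion(c(1, 0), c(1, 0))),
                   c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
  set.seed(421)
  y <- rbinom(200, 1, 0.3)
  p <- rbinom(200, 1, 0.5)
  got <- confusion(y, p)
  want <- naive_confusion(y, p)
  expect_equal(unclass(got)[names(want)], want)
  flipped <- confusion(y, 1L - p)
  expect_identical(flipped[["TP"]], got[["FN"]])
  expect_identical(flipped[["FN"]], got[["TP"]])
  expect_identical(flipped[["FP"]], got[["TN"]])
  expect_identical(flipped[["TN"]], got[["FP"]])
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metric formulas and zero-denominator conventions hold", {
  perfect <- classification_metrics(confusion(c(1, 0), c(1, 0)))
  expect_equal(unname(perfect), c(1, 0, 1, 1, 1))
  # no positive predictions: Precision defined as 1, F1 follows TPR
  m <- classification_metrics(c(TP = 0, FP = 0, FN = 5, TN = 10))
  expect_equal(m[["Precision"]], 1)
  expect_equal(m[["F1"]], 0)
  expect_equal(m[["Specificity"]], 1 - m[["FPR"]], tolerance = 1e-12)
  expect_error(classification_metrics(c(TP = 0, FP = 1, FN = 0, TN = 3)),
               "no positive")
})

test_that("specificity complements the false positive rate on random counts", {
  set.seed(422)
  for (rep in seq_len(50)) {
    y <- rbinom(60, 1, 0.4)
    p <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- classification_metrics(confusion(y, p))
    expect_equal(m[["Specificity"]] + m[["FPR"]], 1, tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity, and degenerate scores behave", {
  r <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ], use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise rank oracle", {
  set.seed(423)
  for (rep in seq_len(100)) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.35))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    expect_equal(roc_auc(y, scores)$auc, mann_whitney_auc(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds balance both classes to within one", {
  y <- c(rep(1, 88), rep(0, 264))
  fold <- fntstack:::stratified_folds(y, 4, seed = 1)
  expect_identical(as.integer(table(fold)), rep(88L, 4))
  for (f in 1:4) {
    expect_equal(sum(y[fold == f] == 1), 22)
    expect_equal(sum(y[fold == f] == 0), 66)
  }
  expect_error(fntstack:::stratified_folds(c(1, rep(0, 20)), 2, 1),
               "stratification")
})

test_that("cross-validation pools fold confusions and honours the oracle model", {
  # features carry the label in column 1, so the "model" that returns
  # column 1 is always correct
  y <- rbinom(120, 1, 0.3)
  X <- cbind(y, matrix(rnorm(120 * 3), ncol = 3))
  res <- cross_validate(X, y,
                        fit_fun = function(X, y, seed) NULL,
                        predict_fun = function(model, X) X[, 1],
                        k = 4, seed = 5)
  expect_equal(unname(res$pooled_metrics), c(1, 0, 1, 1, 1))
  expect_equal(res$auc, 1)
  # fold confusions sum to the pooled confusion
  per_fold <- lapply(1:4, function(f)
    confusion(y[res$fold == f],
              as.integer(res$scores[res$fold == f] >= 0.5)))
  summed <- Reduce(`+`, lapply(per_fold, unclass))
  expect_equal(unclass(res$pooled_counts)[names(summed)], summed)
})

test_that("cross-validation is reproducible from its seed", {
  set.seed(424)
  y <- rbinom(80, 1, 0.4)
  X <- matrix(rnorm(80 * 4), ncol = 4)
  run <- function() cross_validate(
    X, y,
    fit_fun = function(X, y, seed) stats::glm.fit(cbind(1, X), y,
                                                  family = binomial()),
    predict_fun = function(m, X)
      stats::plogis(cbind(1, X) %*% m$coefficients),
    k = 5, seed = 77)
  expect_identical(run()$scores, run()$scores)
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(425)
  for (rep in seq_len(20)) {
    y <- c(1, 0, rbinom(48, 1, 0.3))
    scores <- round(runif(50), 2)
    want <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_auc(y, scores)$auc, want, tolerance = 1e-12)
  }
})
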