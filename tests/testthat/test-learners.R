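# The nine base learners as confidence-emitting units, and the out-of-fold
# stacking confidence matrix.

test_that("the nine learner names are fixed and ordered", {
  expect_identical(learner_names(),
                   c("gcforest", "svm", "rf", "adaboost", "dtree", "gbdt",
                     "knn", "logreg", "nbayes"))
  expect_error(fit_learner("mlp", matrix(rnorm(40), ncol = 2),
                           rep(c(0, 1), 10)), "unknown learner")
})

test_that("every learner emits confidences in [0, 1] and learns separable blobs", {
  d <- generate_dataset(dataset_spec(n_pos = 50, n_neg = 50, m = 8,
                                     structure = "blobs", noise_sd = 0.4,
                                     seed = 21))
  X <- d$features
  y <- d$label
  fold <- fntstack:::stratified_folds(y, 2, 3)
  tr <- fold == 1
  te <- fold == 2
  params <- list(gcforest = list(control = tiny_gcforest()))
  for (nm in learner_names()) {
    fitted <- fit_learner(nm, X[tr, ], y[tr], seed = 11,
                          params = if (is.null(params[[nm]])) list()
                          else params[[nm]])
    conf <- learner_confidence(fitted, X[te, ])
    expect_true(all(conf >= 0 & conf <= 1), info = nm)
    expect_gte(mean(as.integer(conf >= 0.5) == y[te]), 0.9)
  }
})

test_that("signal-free features yield near-prior confidences", {
  set.seed(441)
  n <- 80
  y <- c(rep(1, 20), rep(0, 60))                 # prior 0.25
  X <- matrix(rnorm(n * 6), ncol = 6)            # pure noise
  params <- list(gcforest = list(control = tiny_gcforest()))
  for (nm in learner_names()) {
    fitted <- fit_learner(nm, X, y, seed = 13,
                          params = if (is.null(params[[nm]])) list()
                          else params[[nm]])
    conf <- learner_confidence(fitted, matrix(rnorm(50 * 6), ncol = 6))
    expect_lt(abs(mean(conf) - 0.25), 0.15, )
  }
})

test_that("out-of-fold confidences have the right shape and stay near the prior without signal", {
  set.seed(442)
  y <- c(rep(1, 20), rep(0, 40))
  X <- matrix(rnorm(60 * 5), ncol = 5)
  learners <- c("svm", "dtree", "knn", "logreg", "nbayes")
  C <- confidence_matrix(X, y, k_inner = 5, seed = 3, learners = learners)
  expect_identical(dim(C), c(60L, 5L))
  expect_identical(colnames(C), learners)
  expect_true(all(C >= 0 & C <= 1))
  # leakage guard: no-signal out-of-fold confidences track the prior
  # (resubstitution stacking would inflate them towards the labels)
  expect_true(all(abs(colMeans(C) - 1 / 3) < 0.12))
  C_resub <- confidence_matrix(X, y, seed = 3, learners = c("knn", "dtree"),
                               protocol = "resub")
  # in-sample confidences separate the classes far more than honest ones
  gap <- function(M) mean(M[y == 1, ]) - mean(M[y == 0, ])
  expect_gt(gap(C_resub), gap(C[, c("knn", "dtree")]) + 0.1)
})

test_that("fold assignment is keyed to row ids, not row order", {
  set.seed(443)
  y <- rbinom(40, 1, 0.5)
  ids <- sprintf("row%02d", 1:40)
  f1 <- fntstack:::stratified_folds(y, 4, seed = 9, ids = ids)
  perm <- sample(40)
  f2 <- fntstack:::stratified_folds(y[perm], 4, seed = 9, ids = ids[perm])
  expect_identical(f2[order(perm)], f1)
})

test_that("the hand-rolled AdaBoost concentrates weight on hard cases and stays bounded", {
  set.seed(444)
  d <- generate_dataset(dataset_spec(n_pos = 40, n_neg = 40, m = 4,
                                     structure = "blobs", noise_sd = 0.6,
                                     seed = 8))
  fit <- fit_learner("adaboost", d$features, d$label, seed = 2)
  conf <- learner_confidence(fit, d$features)
  expect_true(all(conf >= 0 & conf <= 1))
  expect_gt(roc_auc(d$label, conf)$auc, 0.9)
  # ensemble of stumps must beat any single stump in-sample
  single <- fit_learner("adaboost", d$features, d$label, seed = 2,
                        params = list(n_rounds = 1))
  expect_gte(roc_auc(d$label, conf)$auc,
             roc_auc(d$label, learner_confidence(single, d$features))$auc)
})
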