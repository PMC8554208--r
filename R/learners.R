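# The nine base classifiers, each exposed as a confidence-emitting unit:
# "confidence" is the positive-class probability in [0, 1].  Library
# implementations are used with their default hyper-parameters (SVM and
# naive Bayes from e1071, random forest from ranger, decision tree from
# rpart, gradient boosting from xgboost, KNN from class, logistic
# regression from stats::glm); gcForest is this package's own cascade
# forest, and AdaBoost (SAMME over depth-1 rpart stumps) is implemented
# here because no AdaBoost package is available.  SVM confidences come from
# e1071's built-in Platt calibration of the margin.

#' The nine base learner names, in canonical order
#'
#' The order fixes the meaning of the confidence-matrix columns c1..c9:
#' gcforest, svm, rf, adaboost, dtree, gbdt, knn, logreg, nbayes.
#'
#' @return Character vector of length 9.
#' @export
learner_names <- function() {
  c("gcforest", "svm", "rf", "adaboost", "dtree", "gbdt", "knn", "logreg",
    "nbayes")
}

as_xy <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y)) {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("y contains a single class", call. = FALSE)
  }
  list(X = X, y = y)
}

# --- AdaBoost (SAMME, depth-1 rpart stumps, 50 rounds) -------------------

fit_adaboost <- function(X, y, n_rounds = 50L, seed = 1L) {
  df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
  w <- rep(1 / nrow(df), nrow(df))
  stumps <- list()
  alphas <- numeric(0)
  with_seed(seed, function() {
    for (m in seq_len(n_rounds)) {
      stump <- rpart::rpart(.y ~ ., data = df, weights = w,
                            method = "class",
                            control = rpart::rpart.control(maxdepth = 1L,
                                                           cp = -1,
                                                           minsplit = 2L,
                                                           xval = 0L))
      pred <- stats::predict(stump, df, type = "class")
      err <- sum(w * (pred != df$.y))
      if (err <= 1e-12) {            # perfect stump: take it and stop
        stumps[[length(stumps) + 1L]] <<- stump
        alphas[[length(alphas) + 1L]] <<- 10
        break
      }
      if (err >= 0.5) break          # no better than chance: stop
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[length(stumps) + 1L]] <<- stump
      alphas[[length(alphas) + 1L]] <<- alpha
      w <<- w * exp(alpha * ifelse(pred != df$.y, 1, -1))
      w <<- w / sum(w)
    }
  })
  if (length(stumps) == 0L) {        # degenerate: fall back to the prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(model, X) {
  if (length(model$stumps) == 0L)
    return(rep(model$prior, nrow(as.matrix(X))))
  df <- data.frame(as.matrix(X))
  # confidence: alpha-weighted mean of the stumps' leaf class-1
  # proportions (a calibrated analogue of the weighted vote; on
  # signal-free data it stays near the class prior)
  num <- 0
  for (m in seq_along(model$stumps)) {
    p <- stats::predict(model$stumps[[m]], df, type = "prob")[, "1"]
    num <- num + model$alphas[[m]] * p
  }
  num / sum(model$alphas)
}

# --- unified fit / confidence interface ----------------------------------

#' Fit one of the nine base learners
#'
#' All learners are used with their library-default hyper-parameters;
#' `params` allows explicit overrides (passed through to the backing
#' implementation; for `"gcforest"` it may carry a [gcforest_control()]).
#'
#' @param name One of [learner_names()].
#' @param X Numeric feature matrix or data frame (no missing values).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed for the stochastic learners.
#' @param params Named list of overrides.
#' @return An object of class `base_learner` usable with
#'   [learner_confidence()].
#' @export
fit_learner <- function(name, X, y, seed = 1L, params = list()) {
  if (!name %in% learner_names())
    stop("unknown learner '", name, "'; valid names: ",
         paste(learner_names(), collapse = ", "), call. = FALSE)
  d <- as_xy(X, y)
  X <- d$X
  y <- d$y
  fit <- switch(
    name,
    gcforest = {
      ctrl <- params$control
      if (is.null(ctrl)) ctrl <- gcforest_control()
      ctrl$seed <- as.integer(seed)
      gcforest_fit(X, y, ctrl)
    },
    svm = with_seed(seed, function()
      suppressWarnings(e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                                  probability = TRUE))),
    rf = ranger::ranger(x = as.data.frame(X), y = factor(y,
                                                         levels = c(0, 1)),
                        probability = TRUE, num.threads = 1L,
                        seed = as.integer(seed), verbose = FALSE),
    adaboost = fit_adaboost(X, y,
                            n_rounds = if (is.null(params$n_rounds)) 50L
                            else params$n_rounds, seed = seed),
    dtree = rpart::rpart(.y ~ ., data = data.frame(X, .y = factor(y)),
                         method = "class"),
    gbdt = {
      nrounds <- if (is.null(params$nrounds)) 100L else params$nrounds
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      with_seed(seed, function()
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         nthread = 1L),
                           data = dtrain, nrounds = nrounds, verbose = 0))
    },
    knn = list(X = X, y = y,
               k = if (is.null(params$k)) 5L else as.integer(params$k),
               seed = as.integer(seed)),
    logreg = suppressWarnings(
      stats::glm(.y ~ ., data = data.frame(X, .y = y),
                 family = stats::binomial())),
    nbayes = e1071::naiveBayes(x = as.data.frame(X),
                               y = factor(y, levels = c(0, 1)))
  )
  structure(list(name = name, fit = fit, n_features = ncol(X)),
            class = "base_learner")
}

#' Positive-class confidence of a fitted base learner
#'
#' @param learner A `base_learner` from [fit_learner()].
#' @param X New feature matrix with the number of columns used at fit time.
#' @return Numeric vector of confidences in [0, 1], one per row.
#' @export
learner_confidence <- function(learner, X) {
  stopifnot(inherits(learner, "base_learner"))
  X <- as.matrix(X)
  if (ncol(X) != learner$n_features)
    stop("X has ", ncol(X), " features; learner was fitted with ",
         learner$n_features, call. = FALSE)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- learner$fit
  conf <- switch(
    learner$name,
    gcforest = predict(fit, X, type = "prob"),
    svm = {
      p <- stats::predict(fit, X, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    rf = stats::predict(fit, data = as.data.frame(X),
                        num.threads = 1L, verbose = FALSE)$predictions[, "1"],
    adaboost = predict_adaboost(fit, X),
    dtree = stats::predict(fit, data.frame(X), type = "prob")[, "1"],
    gbdt = stats::predict(fit, xgboost::xgb.DMatrix(X)),
    knn = with_seed(fit$seed, function() {
      p <- class::knn(train = fit$X, test = X,
                      cl = factor(fit$y, levels = c(0, 1)),
                      k = min(fit$k, nrow(fit$X)), prob = TRUE)
      pr <- attr(p, "prob")
      ifelse(p == "1", pr, 1 - pr)
    }),
    logreg = stats::predict(fit, data.frame(X), type = "response"),
    nbayes = stats::predict(fit, as.data.frame(X), type = "raw")[, "1"]
  )
  conf <- as.numeric(conf)
  pmin(pmax(conf, 0), 1)
}

#' Out-of-fold stacking confidences for the nine base learners
#'
#' Produces the n x 9 confidence matrix used to train the flexible neural
#' tree meta-learner.  Row i's confidences come from models whose training
#' folds excluded row i (stratified `k_inner`-fold), which keeps the
#' meta-learner free of resubstitution leakage; `protocol = "resub"`
#' instead fits each learner once on all rows and scores them in-sample.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels (0/1).
#' @param k_inner Number of inner stacking folds (default 5).
#' @param seed Integer seed (folds and learner fits derive from it).
#' @param learners Learner names (default all nine, canonical order).
#' @param params Named list of per-learner override lists.
#' @param protocol `"oof"` (default) or `"resub"`.
#' @param ids Row identifiers the fold assignment is keyed to (default row
#'   positions); permuting rows together with their ids leaves each id's
#'   fold unchanged.
#' @return Matrix n x length(learners) with learner names as columns, all
#'   entries in [0, 1].
#' @export
confidence_matrix <- function(X, y, k_inner = 5L, seed = 1L,
                              learners = learner_names(), params = list(),
                              protocol = c("oof", "resub"),
                              ids = seq_along(y)) {
  protocol <- match.arg(protocol)
  d <- as_xy(X, y)
  X <- d$X
  y <- d$y
  C <- matrix(NA_real_, nrow(X), length(learners),
              dimnames = list(NULL, learners))
  if (protocol == "resub") {
    for (li in seq_along(learners)) {
      nm <- learners[[li]]
      fitted <- fit_learner(nm, X, y, seed = derive_seed(seed, li),
                            params = if (is.null(params[[nm]])) list()
                            else params[[nm]])
      C[, li] <- learner_confidence(fitted, X)
    }
    return(C)
  }
  fold <- stratified_folds(y, k_inner, derive_seed(seed, 0), ids = ids)
  for (f in seq_len(k_inner)) {
    tr <- fold != f
    te <- fold == f
    for (li in seq_along(learners)) {
      nm <- learners[[li]]
      fitted <- fit_learner(nm, X[tr, , drop = FALSE], y[tr],
                            seed = derive_seed(seed, f * 100 + li),
                            params = if (is.null(params[[nm]])) list()
                            else params[[nm]])
      C[te, li] <- learner_confidence(fitted, X[te, , drop = FALSE])
    }
  }
  C
}
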