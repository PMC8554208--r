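# Cross-validated comparison of the FNT stacker, the nine single
# classifiers and the two baseline ensembles under a shared fold
# assignment.

#' Cross-validated comparison of stacker, single learners and baselines
#'
#' Runs one stratified k-fold protocol in which every method sees the same
#' folds.  Per fold, the nine base learners are fitted once on the training
#' split; their held-out confidences score the single learners and feed the
#' averaged and voting baselines, and the FNT meta-learner (evolved on the
#' training split's inner out-of-fold confidence matrix) maps them to the
#' stacker's confidence.  Metrics are pooled over folds (summed confusions,
#' concatenated scores for the ROC).
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels (0/1).
#' @param k Number of folds.
#' @param seed Integer seed; folds, learner fits and evolution derive from
#'   it.
#' @param evolution [fnt_control()] for the meta-learner search.
#' @param k_inner Inner stacking folds (default 5).
#' @param learner_params Per-learner override lists (see [fit_learner()]).
#' @param threshold Decision threshold (default 0.5); the voting baseline
#'   scores rows by the fraction of positive votes, so thresholding that
#'   fraction at 0.5 is the majority vote.
#' @param methods Which methods to score: `"all"` (default), or a character
#'   vector drawn from `c("fnt_stack", learner_names(), "averaged",
#'   "voting")`.
#' @return List of class `method_comparison`: `k`, `fold`, `scores`
#'   (n x methods matrix of held-out confidences), `metrics` (methods x 5),
#'   `auc` (named vector), `pooled_counts`.
#' @export
compare_methods <- function(X, y, k, seed = 1L, evolution = fnt_control(),
                            k_inner = 5L, learner_params = list(),
                            threshold = 0.5, methods = "all") {
  d <- as_xy(X, y)
  X <- d$X
  y <- d$y
  all_methods <- c("fnt_stack", learner_names(), "averaged", "voting")
  if (identical(methods, "all")) methods <- all_methods
  stopifnot(all(methods %in% all_methods))
  need_stack <- "fnt_stack" %in% methods
  fold <- stratified_folds(y, k, derive_seed(seed, 0))
  scores <- matrix(NA_real_, length(y), length(methods),
                   dimnames = list(NULL, methods))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- fold == f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    Xte <- X[te, , drop = FALSE]
    learners <- lapply(seq_along(learner_names()), function(li) {
      nm <- learner_names()[[li]]
      fit_learner(nm, Xtr, ytr, seed = derive_seed(seed, f * 100 + li),
                  params = if (is.null(learner_params[[nm]])) list()
                  else learner_params[[nm]])
    })
    names(learners) <- learner_names()
    Cte <- sapply(learners, function(l) learner_confidence(l, Xte))
    if (sum(te) == 1L) Cte <- matrix(Cte, nrow = 1L,
                                     dimnames = list(NULL,
                                                     learner_names()))
    for (nm in intersect(methods, learner_names()))
      scores[te, nm] <- Cte[, nm]
    if ("averaged" %in% methods)
      scores[te, "averaged"] <- averaged_ensemble(Cte)
    if ("voting" %in% methods)
      scores[te, "voting"] <- rowMeans(Cte >= threshold)
    if (need_stack) {
      Ctr <- confidence_matrix(Xtr, ytr, k_inner = k_inner,
                               seed = derive_seed(seed, f * 1000),
                               params = learner_params)
      ctrl <- evolution
      ctrl$seed <- as.integer(derive_seed(seed, f * 1000 + 1) %% 2^31)
      evo <- fnt_evolve(Ctr, ytr, ctrl)
      scores[te, "fnt_stack"] <- fnt_evaluate(evo$best_tree, Cte,
                                              validate = FALSE)
    }
  }
  metrics <- matrix(NA_real_, length(methods), 5L,
                    dimnames = list(methods, c("TPR", "FPR", "Precision",
                                               "Specificity", "F1")))
  auc <- stats::setNames(numeric(length(methods)), methods)
  counts <- list()
  for (nm in methods) {
    cts <- confusion(y, as.integer(scores[, nm] >= threshold))
    metrics[nm, ] <- classification_metrics(cts)
    auc[[nm]] <- roc_auc(y, scores[, nm])$auc
    counts[[nm]] <- cts
  }
  structure(list(k = k, fold = fold, scores = scores, metrics = metrics,
                 auc = auc, pooled_counts = counts),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(x$k, "-fold cross-validated comparison\n", sep = "")
  tab <- cbind(round(x$metrics, 6), AUC = round(x$auc, 6))
  print(tab)
  invisible(x)
}
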