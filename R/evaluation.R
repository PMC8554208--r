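# Confusion-matrix metrics, ROC/AUC, and stratified k-fold cross-validation.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return Named integer vector `c(TP, FP, FN, TN)` of class `confusion`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  structure(c(TP = sum(y_true == 1L & y_pred == 1L),
              FP = sum(y_true == 0L & y_pred == 1L),
              FN = sum(y_true == 1L & y_pred == 0L),
              TN = sum(y_true == 0L & y_pred == 0L)),
            class = "confusion")
}

#' Classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), Precision = TP/(TP+FP) (defined as 1
#' when no positive predictions are made), Specificity = TN/(FP+TN) = 1 -
#' FPR, and F1 = harmonic mean of Precision and TPR (0 when both are 0).
#'
#' @param counts A `confusion` object, or a named vector with TP, FP, FN,
#'   TN entries.
#' @return Named numeric vector `c(TPR, FPR, Precision, Specificity, F1)`.
#' @examples
#' classification_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  if (tp + fn == 0L) stop("no positive cases in y_true", call. = FALSE)
  if (fp + tn == 0L) stop("no negative cases in y_true", call. = FALSE)
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  f1 <- if (precision + tpr == 0) 0 else
    2 * precision * tpr / (precision + tpr)
  c(TPR = tpr, FPR = fpr, Precision = precision,
    Specificity = tn / (fp + tn), F1 = f1)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' positive at score >= threshold), yielding a monotone (FPR, TPR) path
#' from (0, 0) to (1, 1); the AUC is the trapezoidal area under that path,
#' which equals the Mann-Whitney rank statistic (ties counted 1/2).
#'
#' @param y_true Binary (0/1) labels, both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return Object of class `roc_curve`: data frame `points` with columns
#'   `fpr`, `tpr`, and `auc`.
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stop("y_true and scores have different lengths", call. = FALSE)
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y_sorted <- y_true[ord]
  s_sorted <- scores[ord]
  # collapse tied scores: one ROC vertex per unique threshold
  last_of_run <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp <- cumsum(y_sorted == 1L)[last_of_run]
  fp <- cumsum(y_sorted == 0L)[last_of_run]
  points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)])
             / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve: ", nrow(x$points), " vertices, AUC = ",
      format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Stratified k-fold cross-validation of a confidence-scoring model
#'
#' Splits the data into stratified folds (per-class fold sizes differ by at
#' most one), fits the model on each training split and scores the held-out
#' fold.  Metrics are reported per fold and pooled: the pooled confusion is
#' the sum of the fold confusions, and the pooled ROC is built from the
#' concatenated out-of-fold scores, matching the convention of reporting
#' one value per k.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels (0/1).
#' @param fit_fun `function(X_train, y_train, seed)` returning a fitted
#'   model.
#' @param predict_fun `function(model, X_new)` returning positive-class
#'   confidences.
#' @param k Number of folds (each fold must retain both classes).
#' @param seed Integer seed; folds and per-fold fits derive from it.
#' @param threshold Decision threshold on the confidence (default 0.5).
#' @return List with `fold_metrics` (k x 5 matrix), `pooled_counts`,
#'   `pooled_metrics`, `roc` (pooled `roc_curve`), `auc`, `scores` and
#'   `fold` (out-of-fold confidences and fold ids in row order).
#' @export
cross_validate <- function(X, y, fit_fun, predict_fun, k, seed = 1L,
                           threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.integer(y)
  fold <- stratified_folds(y, k, derive_seed(seed, 0))
  scores <- numeric(length(y))
  fold_metrics <- matrix(NA_real_, k, 5L,
                         dimnames = list(paste0("fold", seq_len(k)),
                                         c("TPR", "FPR", "Precision",
                                           "Specificity", "F1")))
  pooled <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- fold == f
    model <- fit_fun(X[tr, , drop = FALSE], y[tr], derive_seed(seed, f))
    scores[te] <- predict_fun(model, X[te, , drop = FALSE])
    counts <- confusion(y[te], as.integer(scores[te] >= threshold))
    fold_metrics[f, ] <- classification_metrics(counts)
    pooled <- pooled + unclass(counts)[names(pooled)]
  }
  class(pooled) <- "confusion"
  roc <- roc_auc(y, scores)
  list(fold_metrics = fold_metrics, pooled_counts = pooled,
       pooled_metrics = classification_metrics(pooled), roc = roc,
       auc = roc$auc, scores = scores, fold = fold)
}
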