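# The flexible-neural-tree stacking ensemble, plus the averaged and voting
# baseline ensembles.
#
# Stacking protocol: the nine base classifiers score every training
# compound out-of-fold (stratified inner folds), the resulting n x 9
# confidence matrix trains the FNT meta-learner by evolutionary search, and
# the nine learners are then refit on all training data for deployment.
# Prediction pushes the deployed learners' confidences through the evolved
# tree; the tree output in (0, 1] is the ensemble confidence, thresholded
# at 0.5 by default.

#' Fit a flexible-neural-tree stacking ensemble
#'
#' @param x Numeric feature matrix or data frame (compounds x descriptors).
#' @param y Binary activity labels (0/1), both classes present.
#' @param evolution An [fnt_control()] describing the evolutionary search
#'   for the meta-learner.
#' @param k_inner Inner stacking folds for the out-of-fold confidence
#'   matrix (default 5).
#' @param protocol `"oof"` (default, leakage-safe) or `"resub"`
#'   (resubstitution confidences).
#' @param learner_params Named list of per-learner override lists, passed
#'   to [fit_learner()].
#' @param threshold Decision threshold on the ensemble confidence.
#' @param seed Integer seed for the stacking folds and learner fits
#'   (default: the evolution seed).
#' @return An object of class `fnt_stack` with the evolved tree, the nine
#'   deployed learners, the training confidence matrix and the protocol
#'   record.
#' @examples
#' \donttest{
#' d <- generate_dataset(dataset_spec(n_pos = 20, n_neg = 60, m = 12,
#'                                    seed = 3))
#' fit <- fnt_stack(d$features, d$label,
#'                  evolution = fnt_control(population_size = 10,
#'                                          generations = 5, seed = 3),
#'                  learner_params = list(
#'                    gcforest = list(control = gcforest_control(
#'                      trees_per_forest = 20))))
#' predict(fit, d$features)[1:5]
#' }
#' @export
fnt_stack <- function(x, y, evolution = fnt_control(), k_inner = 5L,
                      protocol = c("oof", "resub"), learner_params = list(),
                      threshold = 0.5, seed = evolution$seed) {
  protocol <- match.arg(protocol)
  stopifnot(threshold > 0, threshold < 1)
  d <- as_xy(x, y)
  C <- confidence_matrix(d$X, d$y, k_inner = k_inner, seed = seed,
                         params = learner_params, protocol = protocol)
  evo <- fnt_evolve(C, d$y, evolution)
  learners <- lapply(seq_along(learner_names()), function(li) {
    nm <- learner_names()[[li]]
    fit_learner(nm, d$X, d$y, seed = derive_seed(seed, 9000 + li),
                params = if (is.null(learner_params[[nm]])) list()
                else learner_params[[nm]])
  })
  names(learners) <- learner_names()
  structure(list(tree = evo$best_tree, evolution = evo, learners = learners,
                 confidence_matrix = C, y = d$y, threshold = threshold,
                 stacking = list(protocol = protocol, k_inner = k_inner,
                                 seed = seed),
                 call = match.call()),
            class = "fnt_stack")
}

# Confidence matrix of the deployed (full-data) learners on new data.
deployed_confidences <- function(object, newdata) {
  C <- sapply(object$learners, function(l) learner_confidence(l, newdata))
  if (is.null(dim(C))) C <- matrix(C, nrow = 1L,
                                   dimnames = list(NULL,
                                                   names(object$learners)))
  C
}

#' Predict from a fitted stacking ensemble
#'
#' @param object An `fnt_stack`.
#' @param newdata Feature matrix with the number of descriptors used at fit
#'   time.
#' @param type `"prob"` (default) for ensemble confidences in (0, 1],
#'   `"class"` for hard 0/1 labels at the fitted threshold, `"confidences"`
#'   for the full n x 9 base-learner confidence matrix.
#' @param ... Unused.
#' @return Numeric vector (or matrix for `"confidences"`).
#' @export
predict.fnt_stack <- function(object, newdata,
                              type = c("prob", "class", "confidences"),
                              ...) {
  type <- match.arg(type)
  C <- deployed_confidences(object, newdata)
  if (type == "confidences") return(C)
  conf <- fnt_evaluate(object$tree, C, validate = FALSE)
  if (type == "prob") conf else as.integer(conf >= object$threshold)
}

#' @export
fitted.fnt_stack <- function(object, ...) {
  fnt_evaluate(object$tree, object$confidence_matrix, validate = FALSE)
}

#' @export
residuals.fnt_stack <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
print.fnt_stack <- function(x, ...) {
  cat("Flexible-neural-tree stacking ensemble\n")
  cat("  base learners: ", paste(names(x$learners), collapse = ", "), "\n",
      sep = "")
  cat("  stacking: ", x$stacking$protocol, " (k_inner = ",
      x$stacking$k_inner, "), threshold ", x$threshold, "\n", sep = "")
  cat("  meta-learner: ", fnt_serialize(x$tree), "\n", sep = "")
  invisible(x)
}

#' @export
summary.fnt_stack <- function(object, ...) {
  conf <- fitted(object)
  counts <- confusion(object$y, as.integer(conf >= object$threshold))
  out <- list(tree = object$tree,
              complexity = fnt_complexity(object$tree),
              best_fitness = object$evolution$best_fitness,
              training_metrics = classification_metrics(counts),
              training_auc = roc_auc(object$y, conf)$auc,
              stacking = object$stacking)
  class(out) <- "summary.fnt_stack"
  out
}

#' @export
print.summary.fnt_stack <- function(x, ...) {
  cat("FNT stacking ensemble summary\n")
  cat("  meta-learner: ", x$complexity[["nodes"]], " nodes, depth ",
      x$complexity[["depth"]], "; evolution fitness ",
      format(x$best_fitness, digits = 6), "\n", sep = "")
  cat("  training (", x$stacking$protocol,
      " confidences): AUC ", format(x$training_auc, digits = 4), "\n",
      sep = "")
  print(round(x$training_metrics, 6))
  invisible(x)
}

#' @export
plot.fnt_stack <- function(x, ...) {
  h <- x$evolution$history
  plot(h$generation, h$mean, type = "l", col = "grey60",
       xlab = "Generation", ylab = "Fitness (RMSE + parsimony)",
       ylim = range(c(h$best, h$mean)), ...)
  graphics::lines(h$generation, h$best, col = "black", lwd = 2)
  graphics::legend("topright", legend = c("population mean", "best"),
                   col = c("grey60", "black"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Averaged baseline ensemble
#'
#' Arithmetic mean of the nine base-learner confidences.
#'
#' @param C Confidence matrix (rows = compounds, columns = learners, values
#'   in [0, 1]).
#' @return Numeric vector of averaged confidences.
#' @export
averaged_ensemble <- function(C) {
  C <- as.matrix(C)
  stopifnot(all(C >= 0 & C <= 1))
  rowMeans(C)
}

#' Voting baseline ensemble
#'
#' Majority vote over the hard labels obtained by thresholding each
#' learner's confidence; with nine voters there are no ties.
#'
#' @param C Confidence matrix in [0, 1].
#' @param threshold Per-learner decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
voting_ensemble <- function(C, threshold = 0.5) {
  C <- as.matrix(C)
  stopifnot(all(C >= 0 & C <= 1))
  votes <- rowSums(C >= threshold)
  as.integer(votes > ncol(C) / 2)
}
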