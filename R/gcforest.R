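# Multi-grained cascade forest (gcForest): sliding-window scanning over the
# descriptor vector followed by a cascade of forest layers whose
# two-dimensional class vectors augment the next layer's input.
#
# Each scanning window of size k yields s = (m - k) + 1 contiguous
# sub-vectors per sample; a completely-random forest (every split uses one
# uniformly random feature and a random threshold, grown to purity) and a
# Breiman-style random forest each score every sub-vector with a 2-class
# probability vector, so a window contributes 4s representation values per
# sample.  The cascade repeats the two-forest layer, feeding each layer the
# scanned representation plus the previous layer's class vectors, until an
# internal cross-validation accuracy stops improving.  Prediction averages
# the final layer's class vectors and takes the arg-max class.

#' Control parameters for the multi-grained cascade forest
#'
#' @param window_sizes Integer vector of sliding-window widths; `NULL`
#'   (default) picks `ceiling(m/4)` and `ceiling(m/2)` at fit time.  Every
#'   window must be smaller than the number of features.
#' @param trees_per_forest Trees in each cascade forest (default 100).
#' @param scan_trees Trees in each scanning forest (default 20; the
#'   scanning stage fits on the pooled sub-instances, where many small
#'   trees are redundant — each sub-vector is scored by every tree of both
#'   forests anyway).
#' @param scan_folds Folds used to produce out-of-fold scanning
#'   probabilities for the training data (limits representation leakage).
#' @param cascade_folds Folds for the cascade's internal accuracy estimate
#'   and out-of-fold augmentation vectors.
#' @param max_layers Hard cap on cascade depth.
#' @param patience Consecutive layers without internal-accuracy improvement
#'   tolerated before growth stops.
#' @param scan_max_instances Cap on pooled sub-instances used to train each
#'   scanning forest; all sub-instances are still scored.  Sliding windows
#'   multiply the training rows by s, and subsampling the pool keeps
#'   scanning affordable without changing the representation's shape.
#' @param seed Integer seed; all forests derive their seeds from it.
#' @return A list of class `gcforest_control`.
#' @export
gcforest_control <- function(window_sizes = NULL, trees_per_forest = 100L,
                             scan_trees = 20L, scan_folds = 3L,
                             cascade_folds = 3L, max_layers = 10L,
                             patience = 1L, scan_max_instances = 1500L,
                             seed = 1L) {
  ctrl <- list(window_sizes = if (is.null(window_sizes)) NULL else
                 as.integer(window_sizes),
               trees_per_forest = as.integer(trees_per_forest),
               scan_trees = as.integer(scan_trees),
               scan_folds = as.integer(scan_folds),
               cascade_folds = as.integer(cascade_folds),
               max_layers = as.integer(max_layers),
               patience = as.integer(patience),
               scan_max_instances = as.integer(scan_max_instances),
               seed = as.integer(seed))
  stopifnot(ctrl$trees_per_forest >= 1L, ctrl$scan_trees >= 1L,
            ctrl$max_layers >= 1L,
            ctrl$patience >= 1L, ctrl$scan_folds >= 2L,
            ctrl$cascade_folds >= 2L)
  class(ctrl) <- "gcforest_control"
  ctrl
}

# Fit one forest; type "crf" = completely-random (one random feature, one
# random threshold per split, grown to purity), "rf" = Gini random forest.
fit_forest <- function(X, y, type, trees, seed) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  yf <- factor(y, levels = c(0, 1))
  if (type == "crf") {
    ranger::ranger(x = df, y = yf, num.trees = trees, probability = TRUE,
                   mtry = 1L, splitrule = "extratrees",
                   num.random.splits = 1L, min.node.size = 1L,
                   num.threads = 1L, seed = seed, verbose = FALSE)
  } else {
    ranger::ranger(x = df, y = yf, num.trees = trees, probability = TRUE,
                   min.node.size = 1L, num.threads = 1L, seed = seed,
                   verbose = FALSE)
  }
}

# Positive/negative class probability matrix (n x 2, columns p0, p1).
forest_probs <- function(forest, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  p <- stats::predict(forest, data = df, num.threads = 1L,
                      verbose = FALSE)$predictions
  cbind(p[, "0"], p[, "1"])
}

# Out-of-fold class probabilities for rows of X, with folds given per row
# group `groups` (sub-instances of one sample share a group and hence a
# fold).  Also returns the full-data forest for new-data transforms.
oof_forest <- function(X, y, groups, group_y, type, trees, folds, seed,
                       max_train = Inf) {
  fold_of_group <- stratified_folds(group_y, folds, derive_seed(seed, 1))
  fold <- fold_of_group[groups]
  probs <- matrix(NA_real_, nrow(X), 2L)
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    if (length(tr) > max_train)
      tr <- with_seed(derive_seed(seed, 100 + f),
                      function() sample(tr, max_train))
    fit <- fit_forest(X[tr, , drop = FALSE], y[tr], type, trees,
                      derive_seed(seed, 10 + f))
    probs[fold == f, ] <- forest_probs(fit, X[fold == f, , drop = FALSE])
  }
  tr <- seq_len(nrow(X))
  if (length(tr) > max_train)
    tr <- with_seed(derive_seed(seed, 99), function() sample(tr, max_train))
  full <- fit_forest(X[tr, , drop = FALSE], y[tr], type, trees,
                     derive_seed(seed, 9))
  list(oof = probs, full = full)
}

# Pool the s = m - k + 1 contiguous sub-vectors of every row of X into an
# (n*s) x k matrix, sub-instance t of sample i at row (i-1)*s + t.
window_pool <- function(X, k) {
  m <- ncol(X)
  s <- m - k + 1L
  idx <- outer(seq_len(s) - 1L, seq_len(k), `+`)    # s x k column indices
  pool <- matrix(NA_real_, nrow(X) * s, k)
  for (t in seq_len(s))
    pool[seq(t, by = s, length.out = nrow(X)), ] <-
      X[, idx[t, ], drop = FALSE]
  pool
}

#' Multi-grained scanning
#'
#' Slides each configured window over the feature vector, scores every
#' sub-vector with a completely-random forest and a random forest, and
#' concatenates all class-probability pairs into the scanned
#' representation.  Training-data probabilities are produced out-of-fold
#' (sub-instances of a sample share its fold) to limit leakage into the
#' cascade.
#'
#' @param X Numeric matrix or data frame, n samples x m features.
#' @param y Binary labels (0/1).
#' @param control A [gcforest_control()].
#' @return An object of class `mg_scan` with elements `representation`
#'   (n x sum(4 s_w) matrix), `windows`, `forests` (full-data forests for
#'   [mg_scan_transform()]) and `m`.
#' @export
mg_scan_fit <- function(X, y, control = gcforest_control()) {
  X <- as.matrix(X)
  m <- ncol(X)
  windows <- control$window_sizes
  if (is.null(windows)) windows <- unique(pmax(1L, c(ceiling(m / 4),
                                                     ceiling(m / 2))))
  if (any(windows >= m) || any(windows < 1L))
    stop("every window size must satisfy 1 <= k < m = ", m, call. = FALSE)
  n <- nrow(X)
  reps <- list()
  forests <- list()
  for (wi in seq_along(windows)) {
    k <- windows[[wi]]
    s <- m - k + 1L
    pool <- window_pool(X, k)
    pool_y <- rep(y, each = s)
    groups <- rep(seq_len(n), each = s)
    blocks <- list()
    forests[[wi]] <- list()
    for (ft in c("crf", "rf")) {
      res <- oof_forest(pool, pool_y, groups, y, ft,
                        control$scan_trees, control$scan_folds,
                        derive_seed(control$seed, 1000 * wi +
                                      ifelse(ft == "crf", 1, 2)),
                        max_train = control$scan_max_instances)
      # n x 2s block: sub-instance probabilities laid out sample-major
      blocks[[ft]] <- matrix(t(res$oof), nrow = n, byrow = TRUE)
      forests[[wi]][[ft]] <- res$full
    }
    reps[[wi]] <- cbind(blocks$crf, blocks$rf)
  }
  structure(list(representation = do.call(cbind, reps), windows = windows,
                 forests = forests, m = m, control = control),
            class = "mg_scan")
}

#' Apply a fitted multi-grained scan to new data
#'
#' @param scan An `mg_scan` object from [mg_scan_fit()].
#' @param X New data with the same number of features as at fit time.
#' @return Representation matrix with the same width as at fit time.
#' @export
mg_scan_transform <- function(scan, X) {
  X <- as.matrix(X)
  if (ncol(X) != scan$m)
    stop("X has ", ncol(X), " features; scan was fitted with ", scan$m,
         call. = FALSE)
  n <- nrow(X)
  reps <- list()
  for (wi in seq_along(scan$windows)) {
    k <- scan$windows[[wi]]
    s <- scan$m - k + 1L
    pool <- window_pool(X, k)
    blocks <- lapply(scan$forests[[wi]], function(f)
      matrix(t(forest_probs(f, pool)), nrow = n, byrow = TRUE))
    reps[[wi]] <- cbind(blocks$crf, blocks$rf)
  }
  do.call(cbind, reps)
}

#' Fit a cascade forest
#'
#' Grows layers of one completely-random forest and one random forest.  The
#' first layer sees the scanned representation `R`; layer t >= 2 sees `R`
#' plus layer t-1's four class-vector values.  Internal k-fold accuracy
#' decides growth: layers are added until accuracy fails to improve for
#' `patience` consecutive layers or `max_layers` is reached, and the
#' cascade is truncated at the best layer.
#'
#' @param R Representation matrix (rows = samples).
#' @param y Binary labels (0/1), both classes present.
#' @param control A [gcforest_control()].
#' @return An object of class `cascade_model` with `layers` (full-data
#'   forest pairs), `n_layers_used`, `stop_reason` and `layer_accuracy`.
#' @export
cascade_fit <- function(R, y, control = gcforest_control()) {
  R <- as.matrix(R)
  if (nrow(R) == 0L) stop("empty representation", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y contains a single class", call. = FALSE)
  layers <- list()
  acc <- numeric(0)
  best_acc <- -Inf
  best_layer <- 0L
  stall <- 0L
  stop_reason <- "max_layers reached"
  Z <- R
  for (t in seq_len(control$max_layers)) {
    seed_t <- derive_seed(control$seed, 5000 + t)
    resA <- oof_forest(Z, y, seq_along(y), y, "crf",
                       control$trees_per_forest, control$cascade_folds,
                       derive_seed(seed_t, 1))
    resB <- oof_forest(Z, y, seq_along(y), y, "rf",
                       control$trees_per_forest, control$cascade_folds,
                       derive_seed(seed_t, 2))
    layers[[t]] <- list(crf = resA$full, rf = resB$full)
    avg <- (resA$oof + resB$oof) / 2
    pred <- as.integer(avg[, 2] >= avg[, 1])   # tie -> positive class
    acc[[t]] <- mean(pred == y)
    if (acc[[t]] > best_acc + 1e-12) {
      best_acc <- acc[[t]]
      best_layer <- t
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) {
        stop_reason <- sprintf(
          "no internal-accuracy improvement for %d layer(s)", stall)
        break
      }
    }
    if (best_acc >= 1 - 1e-12 && t >= 1L) {
      stop_reason <- "internal accuracy reached 1"
      break
    }
    Z <- cbind(R, resA$oof, resB$oof)
  }
  n_used <- max(best_layer, 1L)
  structure(list(layers = layers[seq_len(n_used)], n_layers_used = n_used,
                 stop_reason = stop_reason,
                 layer_accuracy = acc, control = control),
            class = "cascade_model")
}

#' Predict from a fitted cascade forest
#'
#' Runs the representation through the retained layers; the final layer's
#' two class vectors are averaged and the predicted label is the arg-max
#' class (ties go to the positive class).
#'
#' @param model A `cascade_model`.
#' @param R Representation matrix with the width used at fit time.
#' @return Matrix with columns `p0`, `p1` (rows sum to 1); attribute
#'   `label` holds the hard labels.
#' @export
cascade_predict <- function(model, R) {
  R <- as.matrix(R)
  Z <- R
  probs <- NULL
  for (t in seq_along(model$layers)) {
    pA <- forest_probs(model$layers[[t]]$crf, Z)
    pB <- forest_probs(model$layers[[t]]$rf, Z)
    probs <- (pA + pB) / 2
    if (t < length(model$layers)) Z <- cbind(R, pA, pB)
  }
  colnames(probs) <- c("p0", "p1")
  attr(probs, "label") <- as.integer(probs[, 2] >= probs[, 1])
  probs
}

#' Fit a multi-grained cascade forest classifier
#'
#' Composition of [mg_scan_fit()] and [cascade_fit()].
#'
#' @param X Numeric feature matrix or data frame.
#' @param y Binary labels (0/1).
#' @param control A [gcforest_control()].
#' @return An object of class `gcforest`.
#' @examples
#' \donttest{
#' d <- generate_dataset(dataset_spec(n_pos = 30, n_neg = 30, m = 12,
#'                                    structure = "blobs", seed = 1))
#' fit <- gcforest_fit(d$features, d$label,
#'                     gcforest_control(trees_per_forest = 20, seed = 1))
#' head(predict(fit, d$features))
#' }
#' @export
gcforest_fit <- function(X, y, control = gcforest_control()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  scan <- mg_scan_fit(X, y, control)
  cascade <- cascade_fit(scan$representation, y, control)
  structure(list(scan = scan, cascade = cascade, control = control),
            class = "gcforest")
}

#' @rdname gcforest_fit
#' @param object A fitted `gcforest`.
#' @param newdata New feature matrix with the same number of columns.
#' @param type `"prob"` for the positive-class confidence, `"class"` for
#'   hard labels.
#' @param ... Unused.
#' @export
predict.gcforest <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  R <- mg_scan_transform(object$scan, as.matrix(newdata))
  probs <- cascade_predict(object$cascade, R)
  if (type == "prob") unname(probs[, 2]) else attr(probs, "label")
}

#' @export
print.gcforest <- function(x, ...) {
  cat("gcForest: windows {", paste(x$scan$windows, collapse = ", "),
      "}, ", x$cascade$n_layers_used, " cascade layer(s)\n", sep = "")
  cat("stop reason: ", x$cascade$stop_reason, "\n", sep = "")
  invisible(x)
}
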