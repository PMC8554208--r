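# Independent oracles used by the test suite.  These are deliberately
# written as naive, separately-structured implementations so they share no
# code path with the package internals they check.

# Naive scalar recursive evaluator for a flexible neural tree node.
naive_eval_node <- function(node, x) {
  if (identical(node$type, "var")) return(x[node$index])
  net <- 0
  for (j in seq_along(node$children))
    net <- net + node$weights[j] * naive_eval_node(node$children[[j]], x)
  exp(-((net - node$center) / node$width)^2)
}

naive_eval_tree <- function(tree, x) naive_eval_node(tree$root, x)

# Mann-Whitney AUC: fraction of (positive, negative) pairs where the
# positive outscores the negative, ties counted one half.
mann_whitney_auc <- function(y, scores) {
  sp <- scores[y == 1]
  sn <- scores[y == 0]
  total <- 0
  for (p in sp)
    total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# Naive confusion counting, one comparison at a time.
naive_confusion <- function(y_true, y_pred) {
  out <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(y_true)) {
    key <- if (y_true[i] == 1 && y_pred[i] == 1) "TP"
    else if (y_true[i] == 0 && y_pred[i] == 1) "FP"
    else if (y_true[i] == 1 && y_pred[i] == 0) "FN"
    else "TN"
    out[key] <- out[key] + 1
  }
  out
}

# Majority label of a 0/1 vector (no ties expected for odd lengths).
mode_vote <- function(bits) {
  as.integer(sum(bits == 1) > sum(bits == 0))
}

# Average two probability pairs and take the arg-max (tie -> positive).
avg_argmax <- function(p1, p2) {
  avg <- (p1 + p2) / 2
  list(avg = avg, label = as.integer(avg[2] >= avg[1]))
}

# Multiset of node kinds in a tree: leaf indices and operator arities.
node_kind_multiset <- function(tree) {
  kinds <- character(0)
  walk <- function(node) {
    if (identical(node$type, "var")) {
      kinds[[length(kinds) + 1L]] <<- paste0("c", node$index)
    } else {
      kinds[[length(kinds) + 1L]] <<- paste0("+", node$arity)
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  sort(kinds)
}

# Cheap gcforest settings for unit tests on tiny fixtures.
tiny_gcforest <- function(seed = 1L) {
  gcforest_control(trees_per_forest = 30L, scan_trees = 10L,
                   max_layers = 3L, seed = seed)
}

# Cheap evolution settings for unit tests.
tiny_evolution <- function(seed = 1L) {
  fnt_control(population_size = 12L, generations = 6L,
              sa_steps_per_temp = 5L, sa_cooling = 0.8, seed = seed)
}
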