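# Evolutionary training of flexible neural trees: genetic-programming-style
# structure search (tournament selection, subtree crossover, four mutation
# kinds, elitism) with simulated-annealing refinement of the continuous
# parameters (weights, centres, widths) of the incumbent champion.

#' Control parameters for flexible neural tree evolution
#'
#' @param population_size Number of trees per generation (>= 2).
#' @param generations Number of generations (>= 1).
#' @param max_depth Maximum tree depth (operators only; a single operator
#'   over leaves has depth 1).
#' @param crossover_rate Probability a selected pair undergoes subtree
#'   crossover.
#' @param mutation_rate Probability each offspring is mutated.
#' @param tournament_size Tournament size for parent selection.
#' @param operator_arities Allowed operator arities; default `2:5`, the
#'   operator set +2..+5.
#' @param sa_initial_temp,sa_cooling,sa_steps_per_temp,sa_min_temp,sa_step_scale
#'   Simulated-annealing schedule: start temperature, geometric cooling
#'   factor in (0,1), proposals per temperature, stop temperature, and the
#'   proposal scale (one Gaussian perturbation of a single parameter with
#'   standard deviation `sa_step_scale * temperature`).
#' @param sa_champion When `"new"` (default) annealing runs on a
#'   generation's champion only if it differs from the last tree annealed;
#'   `"always"` re-anneals every generation; `"never"` disables annealing.
#' @param parsimony_coefficient Penalty per tree node added to the
#'   root-mean-square-error fitness (lower fitness is better).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A list of class `fnt_control`.
#' @export
fnt_control <- function(population_size = 50L, generations = 100L,
                        max_depth = 4L, crossover_rate = 0.8,
                        mutation_rate = 0.3, tournament_size = 3L,
                        operator_arities = 2:5,
                        sa_initial_temp = 1.0, sa_cooling = 0.95,
                        sa_steps_per_temp = 20L, sa_min_temp = 1e-3,
                        sa_step_scale = 0.5,
                        sa_champion = c("new", "always", "never"),
                        parsimony_coefficient = 1e-3, seed = 1L) {
  ctrl <- list(population_size = as.integer(population_size),
               generations = as.integer(generations),
               max_depth = as.integer(max_depth),
               crossover_rate = crossover_rate,
               mutation_rate = mutation_rate,
               tournament_size = as.integer(tournament_size),
               operator_arities = as.integer(operator_arities),
               sa_initial_temp = sa_initial_temp, sa_cooling = sa_cooling,
               sa_steps_per_temp = as.integer(sa_steps_per_temp),
               sa_min_temp = sa_min_temp, sa_step_scale = sa_step_scale,
               sa_champion = match.arg(sa_champion),
               parsimony_coefficient = parsimony_coefficient,
               seed = as.integer(seed))
  stopifnot(ctrl$population_size >= 2L, ctrl$generations >= 1L,
            ctrl$crossover_rate >= 0, ctrl$crossover_rate <= 1,
            ctrl$mutation_rate >= 0, ctrl$mutation_rate <= 1,
            length(ctrl$operator_arities) >= 1L,
            all(ctrl$operator_arities >= 2L),
            ctrl$sa_cooling > 0, ctrl$sa_cooling < 1,
            ctrl$sa_min_temp > 0, ctrl$sa_min_temp < ctrl$sa_initial_temp,
            ctrl$parsimony_coefficient >= 0)
  class(ctrl) <- "fnt_control"
  ctrl
}

# Random grow-method subtree: a node at `depth` whose children become
# leaves with probability sqrt(depth/max_depth) (leaf-heavy so initial
# trees stay small; parsimony pressure handles the rest), forced leaves
# once max_depth is reached.
random_subtree <- function(n_inputs, operator_arities, max_depth, depth) {
  if (depth > max_depth) return(fnt_var(sample.int(n_inputs, 1L)))
  arity <- operator_arities[[sample.int(length(operator_arities), 1L)]]
  p_leaf <- sqrt(depth / max_depth)
  children <- lapply(seq_len(arity), function(j) {
    if (depth >= max_depth || stats::runif(1) < p_leaf)
      fnt_var(sample.int(n_inputs, 1L))
    else
      random_subtree(n_inputs, operator_arities, max_depth, depth + 1L)
  })
  fnt_op(stats::runif(arity, -1, 1), stats::runif(1, 0, 1),
         stats::runif(1, 0.1, 1), children)
}

#' Draw a random flexible neural tree
#'
#' Grow initialisation: the root is always an operator; each child becomes
#' a leaf with probability `sqrt(depth / max_depth)` (increasing with
#' depth) and is forced to a leaf at `max_depth`.  Weights are
#' Uniform(-1, 1), centres Uniform(0, 1), widths Uniform(0.1, 1).  Uses
#' the current R random-number stream.
#'
#' @param n_inputs Number of input variables.
#' @param operator_arities Allowed arities.
#' @param max_depth Depth cap.
#' @return A valid `fnt_tree`.
#' @export
fnt_random_tree <- function(n_inputs, operator_arities = 2:5,
                            max_depth = 4L) {
  if (length(operator_arities) == 0L)
    stop("operator_arities must be non-empty", call. = FALSE)
  root <- random_subtree(n_inputs, as.integer(operator_arities),
                         as.integer(max_depth), 1L)
  fnt_tree(root, n_inputs, operator_arities = operator_arities,
           max_depth = max_depth)
}

# Enumerate node paths; a path is an integer vector of child positions
# (length 0 = root).
node_paths <- function(node) {
  acc <- list(integer(0))
  if (is_op(node)) {
    for (j in seq_along(node$children)) {
      for (p in node_paths(node$children[[j]]))
        acc[[length(acc) + 1L]] <- c(j, p)
    }
  }
  acc
}

get_node <- function(node, path) {
  for (j in path) node <- node$children[[j]]
  node
}

set_node <- function(node, path, replacement) {
  if (length(path) == 0L) return(replacement)
  node$children[[path[[1L]]]] <-
    set_node(node$children[[path[[1L]]]], path[-1L], replacement)
  node
}

# Truncate any operator deeper than max_depth to a random leaf.
repair_depth <- function(node, n_inputs, max_depth, depth) {
  if (is_var(node)) return(node)
  if (depth > max_depth) return(fnt_var(sample.int(n_inputs, 1L)))
  node$children <- lapply(node$children, repair_depth, n_inputs = n_inputs,
                          max_depth = max_depth, depth = depth + 1L)
  node
}

#' Subtree crossover between two flexible neural trees
#'
#' A uniformly chosen subtree in each parent is exchanged.  Offspring that
#' would exceed the depth cap are repaired by truncating too-deep operators
#' to random leaves; an offspring left with a bare-leaf root is re-rooted by
#' keeping the donor operator above it intact (the swap is retried at the
#' root level), so both children always satisfy the root-operator rule.
#'
#' @param parent1,parent2 Valid `fnt_tree`s with the same `n_inputs`.
#' @return List of two offspring `fnt_tree`s; parents are unmodified.
#' @export
fnt_crossover <- function(parent1, parent2) {
  stopifnot(inherits(parent1, "fnt_tree"), inherits(parent2, "fnt_tree"),
            parent1$n_inputs == parent2$n_inputs)
  p1 <- node_paths(parent1$root)
  p2 <- node_paths(parent2$root)
  path1 <- p1[[sample.int(length(p1), 1L)]]
  path2 <- p2[[sample.int(length(p2), 1L)]]
  sub1 <- get_node(parent1$root, path1)
  sub2 <- get_node(parent2$root, path2)
  # A leaf swapped to the root would break the operator-root invariant;
  # swap whole trees instead in that corner case.
  if ((length(path1) == 0L && is_var(sub2)) ||
      (length(path2) == 0L && is_var(sub1))) {
    path1 <- integer(0)
    path2 <- integer(0)
    sub1 <- parent1$root
    sub2 <- parent2$root
  }
  c1 <- parent1
  c2 <- parent2
  c1$root <- repair_depth(set_node(parent1$root, path1, sub2),
                          parent1$n_inputs, parent1$max_depth, 1L)
  c2$root <- repair_depth(set_node(parent2$root, path2, sub1),
                          parent2$n_inputs, parent2$max_depth, 1L)
  list(c1, c2)
}

#' Mutate a flexible neural tree
#'
#' One of four equiprobable mutation kinds is applied: (i) replace a random
#' subtree with a fresh random subtree grown within the remaining depth
#' budget; (ii) reassign a random leaf's variable index; (iii) change a
#' random operator's arity, padding with fresh leaves/weights or truncating;
#' (iv) Gaussian jitter (sd 0.1) of one operator's weights, centre and
#' width.  The result is always valid and within the depth cap.
#'
#' @param tree A valid `fnt_tree`.
#' @return A mutated `fnt_tree`.
#' @export
fnt_mutate <- function(tree) {
  stopifnot(inherits(tree, "fnt_tree"))
  kind <- sample.int(4L, 1L)
  paths <- node_paths(tree$root)
  depths <- vapply(paths, length, integer(1))
  ops <- paths[vapply(paths, function(p) is_op(get_node(tree$root, p)),
                      logical(1))]
  leaves <- paths[vapply(paths, function(p) is_var(get_node(tree$root, p)),
                         logical(1))]
  if (kind == 1L) {           # subtree replacement
    i <- sample.int(length(paths), 1L)
    path <- paths[[i]]
    at_depth <- length(path) + 1L   # operator depth a replacement would have
    replacement <- if (length(path) > 0L && stats::runif(1) < 0.5)
      fnt_var(sample.int(tree$n_inputs, 1L))
    else
      random_subtree(tree$n_inputs, tree$operator_arities,
                     tree$max_depth, min(at_depth, tree$max_depth))
    tree$root <- repair_depth(set_node(tree$root, path, replacement),
                              tree$n_inputs, tree$max_depth, 1L)
  } else if (kind == 2L) {    # leaf index change
    path <- leaves[[sample.int(length(leaves), 1L)]]
    tree$root <- set_node(tree$root, path,
                          fnt_var(sample.int(tree$n_inputs, 1L)))
  } else if (kind == 3L) {    # arity change
    path <- ops[[sample.int(length(ops), 1L)]]
    node <- get_node(tree$root, path)
    choices <- setdiff(tree$operator_arities, node$arity)
    if (length(choices)) {
      new_arity <- choices[[sample.int(length(choices), 1L)]]
      if (new_arity > node$arity) {
        extra <- new_arity - node$arity
        node$children <- c(node$children,
                           lapply(seq_len(extra), function(j)
                             fnt_var(sample.int(tree$n_inputs, 1L))))
        node$weights <- c(node$weights, stats::runif(extra, -1, 1))
      } else {
        node$children <- node$children[seq_len(new_arity)]
        node$weights <- node$weights[seq_len(new_arity)]
      }
      node$arity <- new_arity
      tree$root <- set_node(tree$root, path, node)
    }
  } else {                    # parameter jitter
    path <- ops[[sample.int(length(ops), 1L)]]
    node <- get_node(tree$root, path)
    node$weights <- node$weights + stats::rnorm(node$arity, 0, 0.1)
    node$center <- node$center + stats::rnorm(1, 0, 0.1)
    b <- node$width + stats::rnorm(1, 0, 0.1)
    node$width <- sign(b + (b == 0)) * max(abs(b), 1e-3)
    tree$root <- set_node(tree$root, path, node)
  }
  tree
}

#' Fitness of a flexible neural tree on labelled confidences
#'
#' Root-mean-square error between the tree's output and the 0/1 labels,
#' plus a parsimony penalty proportional to node count.  Lower is better.
#'
#' @param tree A valid `fnt_tree`.
#' @param C Numeric matrix (or data frame) of input vectors, one row per
#'   case, `n_inputs` columns.
#' @param y Binary labels (0/1), one per row of `C`.
#' @param parsimony Penalty per node (default 0).
#' @return A single number; 0 is a perfect, penalty-free fit.
#' @export
fnt_fitness <- function(tree, C, y, parsimony = 0) {
  if (is.data.frame(C)) C <- as.matrix(C)
  y <- as.numeric(y)
  if (nrow(C) != length(y))
    stop("C has ", nrow(C), " rows but y has length ", length(y),
         call. = FALSE)
  out <- fnt_evaluate(tree, C, validate = FALSE)
  sqrt(mean((out - y)^2)) + parsimony * fnt_complexity(tree)[["nodes"]]
}

# --- flat tree engine for simulated annealing ----------------------------
# The structure is frozen during annealing, so the tree is flattened once
# into post-order arrays; a single-parameter proposal then only needs the
# perturbed node and its ancestor chain re-evaluated.

flatten_tree <- function(root) {
  nodes <- list()
  parent <- integer(0)
  rec <- function(node) {
    if (is_var(node)) {
      nodes[[length(nodes) + 1L]] <<- list(type = "var",
                                           index = node$index)
      parent[[length(nodes)]] <<- 0L
      return(length(nodes))
    }
    child_ids <- vapply(node$children, rec, integer(1))
    nodes[[length(nodes) + 1L]] <<- list(type = "op",
                                         weights = node$weights,
                                         center = node$center,
                                         width = node$width,
                                         children = child_ids)
    id <- length(nodes)
    parent[child_ids] <<- id
    parent[[id]] <<- 0L
    id
  }
  rec(root)
  list(nodes = nodes, parent = parent)
}

flat_eval_node <- function(flat, i, O, X) {
  nd <- flat$nodes[[i]]
  if (nd$type == "var") return(X[, nd$index])
  net <- 0
  for (j in seq_along(nd$children))
    net <- net + nd$weights[[j]] * O[, nd$children[[j]]]
  exp(-((net - nd$center) / nd$width)^2)
}

flat_eval_all <- function(flat, X) {
  O <- matrix(NA_real_, nrow(X), length(flat$nodes))
  for (i in seq_along(flat$nodes)) O[, i] <- flat_eval_node(flat, i, O, X)
  O
}

# Indices of node i and its ancestors up to the root, in evaluation order.
ancestor_chain <- function(flat, i) {
  chain <- i
  while (flat$parent[[i]] != 0L) {
    i <- flat$parent[[i]]
    chain <- c(chain, i)
  }
  chain
}

# Write refined parameters back into the nested tree (same post-order).
write_back_params <- function(node, flat, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  if (is_var(node)) {
    counter$i <- counter$i + 1L
    return(node)
  }
  node$children <- lapply(node$children, write_back_params, flat = flat,
                          counter = counter)
  counter$i <- counter$i + 1L
  nd <- flat$nodes[[counter$i]]
  node$weights <- nd$weights
  node$center <- nd$center
  node$width <- nd$width
  node
}

#' Simulated-annealing refinement of tree parameters
#'
#' The tree structure is fixed; weights, centres and widths are refined by
#' simulated annealing.  Each proposal perturbs one uniformly chosen
#' parameter by a Gaussian step with standard deviation
#' `sa_step_scale * temperature`; improvements are always accepted,
#' deteriorations with probability `exp(-delta / temperature)`; the
#' temperature cools geometrically until `sa_min_temp`.  The best tree seen
#' (including the input) is returned, so fitness never worsens.
#'
#' @param tree A valid `fnt_tree`.
#' @param C,y Labelled confidences as in [fnt_fitness()].
#' @param control An [fnt_control()] list (annealing schedule fields used).
#' @return The refined `fnt_tree`.
#' @export
fnt_anneal <- function(tree, C, y, control = fnt_control()) {
  if (is.data.frame(C)) C <- as.matrix(C)
  y <- as.numeric(y)
  pc <- control$parsimony_coefficient
  flat <- flatten_tree(tree$root)
  n_nodes <- length(flat$nodes)
  penalty <- pc * n_nodes
  root_id <- n_nodes                      # post-order: root is last
  O <- flat_eval_all(flat, C)
  fit_of <- function(out) sqrt(mean((out - y)^2)) + penalty
  f_current <- fit_of(O[, root_id])
  # flat slots: (node id, field, index) over operator nodes
  slots <- list()
  for (i in seq_len(n_nodes)) {
    nd <- flat$nodes[[i]]
    if (nd$type != "op") next
    for (j in seq_along(nd$weights))
      slots[[length(slots) + 1L]] <- list(id = i, field = "weights",
                                          index = j)
    slots[[length(slots) + 1L]] <- list(id = i, field = "center",
                                        index = 1L)
    slots[[length(slots) + 1L]] <- list(id = i, field = "width", index = 1L)
  }
  best_flat <- flat
  f_best <- f_current
  temp <- control$sa_initial_temp
  while (temp > control$sa_min_temp) {
    for (s in seq_len(control$sa_steps_per_temp)) {
      slot <- slots[[sample.int(length(slots), 1L)]]
      nd <- flat$nodes[[slot$id]]
      old_val <- nd[[slot$field]][[slot$index]]
      new_val <- old_val + stats::rnorm(1, 0, control$sa_step_scale * temp)
      if (slot$field == "width")
        new_val <- sign(new_val + (new_val == 0)) * max(abs(new_val), 1e-3)
      nd[[slot$field]][[slot$index]] <- new_val
      flat$nodes[[slot$id]] <- nd
      chain <- ancestor_chain(flat, slot$id)
      old_cols <- O[, chain, drop = FALSE]
      for (i in chain) O[, i] <- flat_eval_node(flat, i, O, C)
      f_cand <- fit_of(O[, root_id])
      delta <- f_cand - f_current
      if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
        f_current <- f_cand
        if (f_current < f_best) {
          best_flat <- flat
          f_best <- f_current
        }
      } else {                            # revert
        nd[[slot$field]][[slot$index]] <- old_val
        flat$nodes[[slot$id]] <- nd
        O[, chain] <- old_cols
      }
    }
    temp <- temp * control$sa_cooling
    # elitist restart: begin each cooled stage from the best state seen,
    # so the hot phase explores around the incumbent instead of drifting
    if (f_best < f_current) {
      flat <- best_flat
      O <- flat_eval_all(flat, C)
      f_current <- f_best
    }
  }
  out <- tree
  out$root <- write_back_params(tree$root, best_flat)
  out
}

# Tournament selection: lowest fitness wins; ties broken by lower node
# count, then first seen.
tournament_pick <- function(fitnesses, nodes, k) {
  idx <- sample.int(length(fitnesses), min(k, length(fitnesses)))
  ord <- order(fitnesses[idx], nodes[idx])
  idx[[ord[[1L]]]]
}

#' Evolve a flexible neural tree on labelled confidences
#'
#' Generational genetic-programming loop with tournament selection, subtree
#' crossover, mutation, elitism (the champion survives unchanged), and
#' simulated-annealing refinement of the champion's parameters.  Fully
#' reproducible from `control$seed`.
#'
#' @param C Numeric matrix or data frame of inputs (e.g. an n x 9
#'   confidence matrix), one row per case.
#' @param y Binary labels (0/1); both classes must be present.
#' @param control An [fnt_control()] list.
#' @return An object of class `fnt_evolution`: `best_tree`,
#'   `best_fitness`, `history` (per-generation best and mean fitness),
#'   `evaluations` (number of fitness evaluations).
#' @examples
#' set.seed(1)
#' C <- matrix(runif(100 * 3), ncol = 3)
#' y <- as.integer(C[, 1] > 0.5)
#' fit <- fnt_evolve(C, y, fnt_control(population_size = 20, generations = 10,
#'                                     seed = 7))
#' fit$best_fitness
#' @export
fnt_evolve <- function(C, y, control = fnt_control()) {
  stopifnot(inherits(control, "fnt_control"))
  if (is.data.frame(C)) C <- as.matrix(C)
  y <- as.numeric(y)
  if (nrow(C) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("y contains a single class; fitness is degenerate", call. = FALSE)
  n_inputs <- ncol(C)
  pc <- control$parsimony_coefficient
  set.seed(control$seed)

  # Seed the population with one monotone single-input tree per input
  # (net = c_j, centre 1, width 0.6: increasing on (0, 1], crosses 0.5 at
  # c_j = 0.5), so the search starts from every base learner's own
  # ranking; the rest of the population is random.
  n_seeded <- min(n_inputs, control$population_size - 1L)
  seeded <- lapply(seq_len(n_seeded), function(j)
    fnt_tree(fnt_op(c(0.5, 0.5), 1, 0.6, list(fnt_var(j), fnt_var(j))),
             n_inputs, operator_arities = control$operator_arities,
             max_depth = control$max_depth))
  pop <- c(seeded,
           lapply(seq_len(control$population_size - n_seeded), function(i)
             fnt_random_tree(n_inputs, control$operator_arities,
                             control$max_depth)))
  fit <- vapply(pop, fnt_fitness, numeric(1), C = C, y = y, parsimony = pc)
  nodes <- vapply(pop, function(t) fnt_complexity(t)[["nodes"]], integer(1))
  evaluations <- length(pop)
  history <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0))
  last_annealed <- ""

  for (gen in seq_len(control$generations)) {
    elite_idx <- order(fit, nodes)[[1L]]
    if (control$sa_champion == "always" ||
        (control$sa_champion == "new" &&
         !identical(fnt_serialize(pop[[elite_idx]]), last_annealed))) {
      refined <- fnt_anneal(pop[[elite_idx]], C, y, control)
      n_temps <- ceiling(log(control$sa_min_temp / control$sa_initial_temp) /
                           log(control$sa_cooling))
      evaluations <- evaluations + n_temps * control$sa_steps_per_temp
      f_refined <- fnt_fitness(refined, C, y, pc)
      if (f_refined <= fit[[elite_idx]]) {
        pop[[elite_idx]] <- refined
        fit[[elite_idx]] <- f_refined
      }
      last_annealed <- fnt_serialize(pop[[elite_idx]])
    }
    history[nrow(history) + 1L, ] <- list(gen, min(fit), mean(fit))
    if (gen == control$generations) break

    new_pop <- list(pop[[order(fit, nodes)[[1L]]]])    # elitism
    while (length(new_pop) < control$population_size) {
      i <- tournament_pick(fit, nodes, control$tournament_size)
      j <- tournament_pick(fit, nodes, control$tournament_size)
      if (stats::runif(1) < control$crossover_rate) {
        kids <- fnt_crossover(pop[[i]], pop[[j]])
      } else {
        kids <- list(pop[[i]], pop[[j]])
      }
      for (kid in kids) {
        if (length(new_pop) >= control$population_size) break
        if (stats::runif(1) < control$mutation_rate) kid <- fnt_mutate(kid)
        new_pop[[length(new_pop) + 1L]] <- kid
      }
    }
    pop <- new_pop
    fit <- vapply(pop, fnt_fitness, numeric(1), C = C, y = y, parsimony = pc)
    nodes <- vapply(pop, function(t) fnt_complexity(t)[["nodes"]],
                    integer(1))
    evaluations <- evaluations + length(pop)
  }

  best_idx <- order(fit, nodes)[[1L]]
  structure(list(best_tree = pop[[best_idx]], best_fitness = fit[[best_idx]],
                 history = history, evaluations = evaluations,
                 control = control),
            class = "fnt_evolution")
}

#' @export
print.fnt_evolution <- function(x, ...) {
  cat("FNT evolution: ", nrow(x$history), " generations, ",
      x$evaluations, " fitness evaluations\n", sep = "")
  cat("best fitness ", format(x$best_fitness, digits = 6), "\n", sep = "")
  print(x$best_tree)
  invisible(x)
}
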