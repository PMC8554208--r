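# Flexible neural trees: representation, evaluation, validation, text form.
#
# A flexible neural tree (FNT) is a tree whose internal nodes are "flexible
# neuron operators" and whose leaves are input variables.  An operator node
# of arity k holds weights w_1..w_k, a centre a and a width b, and computes
#
#   net = sum_j w_j * o_j        (o_j = output of child j)
#   out = exp(-((net - a) / b)^2)
#
# so every operator output lies in (0, 1].  Leaves pass through the input
# variable they index.  The tree is a cross-layer network: a variable may
# appear under any operator, at any depth, any number of times, or not at
# all (implicit input selection).

# Width guard: the operator divides by b, so |b| below this is rejected.
FNT_B_FLOOR <- 1e-6

#' Variable (leaf) node of a flexible neural tree
#'
#' @param index 1-based position into the input vector; variable `index = j`
#'   is rendered `cj` in the textual tree form.
#' @return A node object of class `fnt_node`.
#' @seealso [fnt_op()], [fnt_tree()]
#' @export
fnt_var <- function(index) {
  index <- as.integer(index)
  stopifnot(length(index) == 1L, !is.na(index))
  structure(list(type = "var", index = index), class = "fnt_node")
}

#' Operator (internal) node of a flexible neural tree
#'
#' @param weights Numeric vector of child weights; its length is the arity.
#' @param center Gaussian centre `a`.
#' @param width Gaussian width `b`; `abs(width)` must stay at or above the
#'   degeneracy floor `1e-6` for the node to be evaluable.
#' @param children List of child nodes, one per weight.
#' @return A node object of class `fnt_node`.
#' @export
fnt_op <- function(weights, center, width, children) {
  structure(list(type = "op", arity = length(weights),
                 weights = as.numeric(weights),
                 center = as.numeric(center), width = as.numeric(width),
                 children = children),
            class = "fnt_node")
}

#' Construct a flexible neural tree
#'
#' @param root Root node, normally an operator node so the model output is a
#'   probability-like score in (0, 1].
#' @param n_inputs Number of input variables the tree may reference.
#' @param operator_arities Allowed operator arities (default 2:5, the
#'   operator set +2..+5).
#' @param max_depth Maximum depth; a single operator over leaves has depth 1.
#' @param allow_leaf_root Permit a bare variable as root (disabled by
#'   default: a leaf root returns the raw input rather than a score).
#' @return An object of class `fnt_tree`.
#' @examples
#' tr <- fnt_tree(fnt_op(c(0.5, 0.5), 0.3, 0.4, list(fnt_var(1), fnt_var(2))),
#'                n_inputs = 9)
#' fnt_evaluate(tr, c(0.6, 0.8, rep(0, 7)))  # exp(-1)
#' @export
fnt_tree <- function(root, n_inputs, operator_arities = 2:5, max_depth = 4L,
                     allow_leaf_root = FALSE) {
  tree <- structure(list(root = root, n_inputs = as.integer(n_inputs),
                         operator_arities = as.integer(sort(operator_arities)),
                         max_depth = as.integer(max_depth),
                         allow_leaf_root = isTRUE(allow_leaf_root)),
                    class = "fnt_tree")
  tree
}

is_var <- function(node) identical(node$type, "var")
is_op  <- function(node) identical(node$type, "op")

#' Validate a flexible neural tree
#'
#' Checks every structural invariant and returns the violations found; it
#' reports rather than throws, so it can be used on candidate trees during
#' evolutionary search.
#'
#' @param tree An `fnt_tree`.
#' @return Character vector of violation messages, each naming the node path
#'   (root, root/2, root/2/1, ...) and the rule broken; `character(0)` for a
#'   well-formed tree.
#' @export
fnt_validate <- function(tree) {
  violations <- character(0)
  note <- function(path, msg) {
    violations[[length(violations) + 1L]] <<- paste0(path, ": ", msg)
  }
  walk <- function(node, path, depth) {
    if (is_var(node)) {
      if (node$index < 1L || node$index > tree$n_inputs)
        note(path, sprintf("variable index %d out of range [1, %d]",
                           node$index, tree$n_inputs))
      return(invisible(NULL))
    }
    if (!is_op(node)) {
      note(path, "unknown node type")
      return(invisible(NULL))
    }
    if (length(node$children) != node$arity)
      note(path, sprintf("arity %d but %d children", node$arity,
                         length(node$children)))
    if (length(node$weights) != node$arity)
      note(path, sprintf("arity %d but %d weights", node$arity,
                         length(node$weights)))
    if (!(node$arity %in% tree$operator_arities))
      note(path, sprintf("arity %d outside allowed set {%s}", node$arity,
                         paste(tree$operator_arities, collapse = ",")))
    if (!is.finite(node$width) || abs(node$width) < FNT_B_FLOOR)
      note(path, sprintf("width |b| = %g below floor %g", abs(node$width),
                         FNT_B_FLOOR))
    if (any(!is.finite(node$weights)) || !is.finite(node$center))
      note(path, "non-finite parameter")
    if (depth > tree$max_depth)
      note(path, sprintf("depth %d exceeds max_depth %d", depth,
                         tree$max_depth))
    for (j in seq_along(node$children))
      walk(node$children[[j]], paste0(path, "/", j), depth + 1L)
    invisible(NULL)
  }
  if (is_var(tree$root) && !tree$allow_leaf_root)
    note("root", "root must be an operator node")
  walk(tree$root, "root", if (is_op(tree$root)) 1L else 0L)
  violations
}

stop_if_invalid <- function(tree) {
  v <- fnt_validate(tree)
  if (length(v))
    stop("invalid flexible neural tree: ", paste(v, collapse = "; "),
         call. = FALSE)
  invisible(tree)
}

# Evaluate a node on a row-wise input matrix X (n x n_inputs); returns a
# length-n vector.  Vectorising over rows keeps evolutionary fitness
# evaluation (thousands of trees x hundreds of rows) cheap in plain R.
eval_node <- function(node, X) {
  if (is_var(node)) return(X[, node$index])
  net <- 0
  for (j in seq_len(node$arity))
    net <- net + node$weights[[j]] * eval_node(node$children[[j]], X)
  if (abs(node$width) < FNT_B_FLOOR)
    stop("degenerate operator width |b| < ", FNT_B_FLOOR, call. = FALSE)
  exp(-((net - node$center) / node$width)^2)
}

#' Evaluate a flexible neural tree
#'
#' Applies the Gaussian neuron-operator recursion from the root.  With an
#' operator root the output is in (0, 1] and is used as a positive-class
#' confidence (decision threshold 0.5 downstream).
#'
#' @param tree An `fnt_tree`.
#' @param x Numeric vector of length `n_inputs`, or a matrix / data frame
#'   with `n_inputs` columns (one input vector per row).
#' @param validate Check the tree first (default TRUE; evolutionary
#'   internals skip the re-check).
#' @return A numeric scalar (vector input) or vector with one value per row.
#' @export
fnt_evaluate <- function(tree, x, validate = TRUE) {
  stopifnot(inherits(tree, "fnt_tree"))
  if (validate) stop_if_invalid(tree)
  if (is.data.frame(x)) x <- as.matrix(x)
  single <- is.null(dim(x))
  if (single) x <- matrix(as.numeric(x), nrow = 1L)
  if (ncol(x) != tree$n_inputs)
    stop("input has ", ncol(x), " columns; tree expects ", tree$n_inputs,
         call. = FALSE)
  out <- eval_node(tree$root, x)
  if (single) out[[1L]] else out
}

#' Size and depth of a flexible neural tree
#'
#' @param tree An `fnt_tree`.
#' @return Named integer vector `c(nodes = , depth = )`; a single operator
#'   over leaves has `nodes = arity + 1` and `depth = 1`.
#' @export
fnt_complexity <- function(tree) {
  stopifnot(inherits(tree, "fnt_tree"))
  count_depth <- function(node) {
    if (is_var(node)) return(c(nodes = 1L, depth = 0L))
    kids <- lapply(node$children, count_depth)
    c(nodes = 1L + sum(vapply(kids, `[[`, integer(1), "nodes")),
      depth = 1L + max(vapply(kids, `[[`, integer(1), "depth")))
  }
  count_depth(tree$root)
}

fmt_num <- function(x) sprintf("%.17g", x)

serialize_node <- function(node) {
  if (is_var(node)) return(sprintf("(c%d)", node$index))
  paste0("(+", node$arity,
         " w=", paste(fmt_num(node$weights), collapse = ","),
         " a=", fmt_num(node$center),
         " b=", fmt_num(node$width), " ",
         paste(vapply(node$children, serialize_node, character(1)),
               collapse = " "),
         ")")
}

#' Textual s-expression form of a flexible neural tree
#'
#' The format is a parenthesised s-expression, e.g.
#' `(+2 w=0.5,0.5 a=0.3 b=0.4 (c1) (c2))`.  Parameters are printed with 17
#' significant digits so that serialise/deserialise round trips are
#' bit-stable.
#'
#' @param tree An `fnt_tree`.
#' @return A single character string.
#' @export
fnt_serialize <- function(tree) {
  stopifnot(inherits(tree, "fnt_tree"))
  serialize_node(tree$root)
}

#' Parse the textual s-expression form back into a tree
#'
#' @param text S-expression produced by [fnt_serialize()] (or written by
#'   hand).
#' @param n_inputs Number of inputs of the reconstructed tree.
#' @param operator_arities,max_depth,allow_leaf_root Passed to [fnt_tree()];
#'   `max_depth = NULL` adopts the parsed tree's own depth.
#' @return An `fnt_tree`; parsing or validation failures raise an error
#'   naming the character position.
#' @export
fnt_deserialize <- function(text, n_inputs, operator_arities = 2:5,
                            max_depth = NULL, allow_leaf_root = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  pos <- 1L
  n <- nchar(text)
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  fail <- function(msg) stop("parse error at position ", pos, ": ", msg,
                             call. = FALSE)
  skip_ws <- function() while (pos <= n && peek() %in% c(" ", "\t", "\n"))
    pos <<- pos + 1L
  expect <- function(ch) {
    if (peek() != ch) fail(paste0("expected '", ch, "'"))
    pos <<- pos + 1L
  }
  read_token <- function() {
    start <- pos
    while (pos <= n && !(peek() %in% c(" ", "\t", "\n", "(", ")")))
      pos <<- pos + 1L
    if (pos == start) fail("expected a token")
    substr(text, start, pos - 1L)
  }
  read_kv <- function(key) {
    skip_ws()
    tok <- read_token()
    if (!startsWith(tok, paste0(key, "=")))
      fail(paste0("expected '", key, "=...'"))
    vals <- suppressWarnings(as.numeric(strsplit(
      sub(paste0("^", key, "="), "", tok), ",", fixed = TRUE)[[1L]]))
    if (any(is.na(vals))) fail(paste0("non-numeric value for '", key, "'"))
    vals
  }
  parse_node <- function() {
    skip_ws()
    expect("(")
    skip_ws()
    head <- read_token()
    if (grepl("^c[0-9]+$", head)) {
      node <- fnt_var(as.integer(sub("^c", "", head)))
      skip_ws()
      expect(")")
      return(node)
    }
    if (!grepl("^\\+[0-9]+$", head)) fail("expected '+<arity>' or 'c<index>'")
    arity <- as.integer(sub("^\\+", "", head))
    w <- read_kv("w")
    if (length(w) != arity) fail(sprintf("arity %d but %d weights", arity,
                                         length(w)))
    a <- read_kv("a")
    b <- read_kv("b")
    children <- vector("list", arity)
    for (j in seq_len(arity)) children[[j]] <- parse_node()
    skip_ws()
    expect(")")
    fnt_op(w, a, b, children)
  }
  root <- parse_node()
  skip_ws()
  if (pos <= n) fail("trailing text after tree")
  tree <- fnt_tree(root, n_inputs, operator_arities = operator_arities,
                   max_depth = 1L, allow_leaf_root = allow_leaf_root)
  d <- fnt_complexity(tree)[["depth"]]
  tree$max_depth <- if (is.null(max_depth)) max(d, 1L) else
    as.integer(max_depth)
  stop_if_invalid(tree)
  tree
}

#' @export
print.fnt_tree <- function(x, ...) {
  cx <- fnt_complexity(x)
  cat("Flexible neural tree: ", cx[["nodes"]], " nodes, depth ",
      cx[["depth"]], ", ", x$n_inputs, " inputs\n", sep = "")
  cat(fnt_serialize(x), "\n")
  invisible(x)
}
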