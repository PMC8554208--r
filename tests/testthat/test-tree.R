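# Flexible neural tree representation, evaluation, validation, text form.

test_that("variable leaves pass through their input and operators follow the Gaussian rule", {
  tree <- fnt_tree(fnt_op(c(0.5, 0.5), 0.7, 1, list(fnt_var(1), fnt_var(2))),
                   n_inputs = 9)
  # leaf identity via a tree that just forwards c3
  leaf_tree <- fnt_tree(fnt_var(3), n_inputs = 9, allow_leaf_root = TRUE)
  x <- c(0, 0, 0.42, rep(0, 6))
  expect_equal(fnt_evaluate(leaf_tree, x), 0.42)
  # Gaussian peak: net = 0.5*0.6 + 0.5*0.8 = 0.7 = a  ->  exp(0) = 1
  expect_equal(fnt_evaluate(tree, c(0.6, 0.8, rep(0, 7))), 1.0)
  # off-centre: a = 0.3, b = 0.4  ->  exp(-((0.7-0.3)/0.4)^2) = exp(-1)
  tree2 <- fnt_tree(fnt_op(c(0.5, 0.5), 0.3, 0.4,
                           list(fnt_var(1), fnt_var(2))), n_inputs = 9)
  expect_equal(fnt_evaluate(tree2, c(0.6, 0.8, rep(0, 7))), exp(-1),
               tolerance = 1e-15)
})

test_that("the worked fixture evaluates to its hand-computed constants", {
  fx <- generate_worked_fixture()
  expect_identical(fnt_validate(fx$tree), character(0))
  got <- fnt_evaluate(fx$tree, fx$inputs)
  expect_equal(got, fx$outputs, tolerance = 1e-12)
  # row-wise matrix evaluation agrees with one-vector-at-a-time calls
  single <- vapply(seq_len(nrow(fx$inputs)), function(i)
    fnt_evaluate(fx$tree, fx$inputs[i, ]), numeric(1))
  expect_identical(got, single)
})

test_that("tree evaluation matches an independent recursive oracle on random trees", {
  set.seed(401)
  for (rep in seq_len(50)) {
    tree <- fnt_random_tree(9, max_depth = sample(2:4, 1))
    X <- matrix(runif(50 * 9), ncol = 9)
    got <- fnt_evaluate(tree, X)
    want <- apply(X, 1, function(x) naive_eval_tree(tree, x))
    expect_equal(got, want, tolerance = 1e-12)
    # operator output stays in (0, 1]
    expect_true(all(got > 0 & got <= 1))
  }
})

test_that("evaluation is continuous in weights, centre and width", {
  set.seed(402)
  tree <- fnt_random_tree(9, max_depth = 3)
  x <- runif(9)
  base <- fnt_evaluate(tree, x)
  h <- 1e-7
  for (field in c("weights", "center", "width")) {
    bumped <- tree
    node <- bumped$root
    node[[field]][[1L]] <- node[[field]][[1L]] + h
    bumped$root <- node
    expect_lt(abs(fnt_evaluate(bumped, x) - base), 1e-4)
  }
})

test_that("validation reports structural violations without throwing", {
  good <- generate_worked_fixture()$tree
  expect_identical(fnt_validate(good), character(0))

  bad_weights <- good
  bad_weights$root$weights <- c(0.1, 0.2, 0.3)    # arity 2, 3 weights
  v <- fnt_validate(bad_weights)
  expect_length(v, 1L)
  expect_match(v, "root.*3 weights")

  bad_index <- fnt_tree(fnt_op(c(1, 1), 0.5, 1,
                               list(fnt_var(10), fnt_var(1))), n_inputs = 9)
  v <- fnt_validate(bad_index)
  expect_length(v, 1L)
  expect_match(v, "out of range")

  thin <- fnt_tree(fnt_op(c(1, 1), 0.5, 1e-9,
                          list(fnt_var(1), fnt_var(2))), n_inputs = 9)
  expect_match(fnt_validate(thin), "below floor")
  expect_error(fnt_evaluate(thin, runif(9)), "invalid")

  leaf_root <- fnt_tree(fnt_var(1), n_inputs = 9)
  expect_match(fnt_validate(leaf_root), "operator node")
})

test_that("complexity counts nodes and depth exactly", {
  flat <- fnt_tree(fnt_op(c(1, 1), 0.5, 1, list(fnt_var(1), fnt_var(2))),
                   n_inputs = 9)
  expect_identical(fnt_complexity(flat), c(nodes = 3L, depth = 1L))
  expect_identical(fnt_complexity(generate_worked_fixture()$tree),
                   c(nodes = 5L, depth = 2L))
  set.seed(403)
  for (rep in seq_len(25)) {
    cx <- fnt_complexity(fnt_random_tree(9))
    expect_gte(cx[["nodes"]], cx[["depth"]] + 1L)
  }
})

test_that("serialization round trips are exact and evaluation-invariant", {
  fx <- generate_worked_fixture()
  text <- fnt_serialize(fx$tree)
  back <- fnt_deserialize(text, n_inputs = 3)
  expect_identical(fnt_serialize(back), text)
  expect_identical(fnt_evaluate(back, fx$inputs),
                   fnt_evaluate(fx$tree, fx$inputs))

  set.seed(404)
  for (rep in seq_len(100)) {
    tree <- fnt_random_tree(9, max_depth = sample(1:4, 1))
    text <- fnt_serialize(tree)
    back <- fnt_deserialize(text, n_inputs = 9)
    expect_identical(fnt_serialize(back), text)
  }
})

test_that("a bare-leaf expression is accepted only under the relaxed root rule", {
  expect_error(fnt_deserialize("(c1)", n_inputs = 9), "operator")
  relaxed <- fnt_deserialize("(c1)", n_inputs = 9, allow_leaf_root = TRUE)
  expect_equal(fnt_evaluate(relaxed, c(0.9, rep(0, 8))), 0.9)
})

test_that("malformed expressions fail with a position", {
  expect_error(fnt_deserialize("(+2 w=0.5 a=0.3 b=0.4 (c1) (c2))", 9),
               "arity 2 but 1 weights")
  expect_error(fnt_deserialize("(+2 w=0.5,0.5 a=x b=0.4 (c1) (c2))", 9),
               "position")
  expect_error(fnt_deserialize("(c1) trailing", 9, allow_leaf_root = TRUE),
               "trailing")
})

test_that("evaluation rejects inputs of the wrong width", {
  fx <- generate_worked_fixture()
  expect_error(fnt_evaluate(fx$tree, c(0.1, 0.2)), "expects 3")
})
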