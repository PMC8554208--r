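# Evolutionary search: random trees, variation operators, fitness,
# annealing, and the generational loop.

test_that("random trees respect the depth cap and are reproducible", {
  set.seed(411)
  shallow <- fnt_random_tree(9, max_depth = 1)
  expect_identical(fnt_complexity(shallow)[["depth"]], 1L)
  expect_true(all(vapply(shallow$root$children,
                         function(ch) identical(ch$type, "var"),
                         logical(1))))

  set.seed(42)
  a <- fnt_random_tree(9)
  set.seed(42)
  b <- fnt_random_tree(9)
  expect_identical(fnt_serialize(a), fnt_serialize(b))

  expect_error(fnt_random_tree(9, operator_arities = integer(0)),
               "non-empty")
})

test_that("random tree generation eventually uses every input variable", {
  set.seed(412)
  seen <- logical(9)
  for (i in seq_len(500)) {
    tree <- fnt_random_tree(9)
    walk <- function(node) {
      if (identical(node$type, "var")) seen[node$index] <<- TRUE
      else for (ch in node$children) walk(ch)
    }
    walk(tree$root)
    if (all(seen)) break
  }
  expect_true(all(seen))
})

test_that("crossover conserves node kinds when no depth repair triggers", {
  set.seed(413)
  for (rep in seq_len(200)) {
    # depth cap far above actual depth, so repair can never trigger
    p1 <- fnt_random_tree(9, max_depth = 3)
    p2 <- fnt_random_tree(9, max_depth = 3)
    p1$max_depth <- 10L
    p2$max_depth <- 10L
    kids <- fnt_crossover(p1, p2)
    expect_identical(fnt_validate(kids[[1]]), character(0))
    expect_identical(fnt_validate(kids[[2]]), character(0))
    expect_identical(sort(c(node_kind_multiset(kids[[1]]),
                            node_kind_multiset(kids[[2]]))),
                     sort(c(node_kind_multiset(p1),
                            node_kind_multiset(p2))))
  }
})

test_that("crossover offspring always validate under the real depth cap", {
  set.seed(414)
  for (rep in seq_len(200)) {
    p1 <- fnt_random_tree(9, max_depth = 4)
    p2 <- fnt_random_tree(9, max_depth = 4)
    kids <- fnt_crossover(p1, p2)
    expect_identical(fnt_validate(kids[[1]]), character(0))
    expect_identical(fnt_validate(kids[[2]]), character(0))
  }
})

test_that("mutation always yields a valid tree and is reproducible", {
  set.seed(415)
  tree <- fnt_random_tree(9)
  for (rep in seq_len(500)) {
    tree2 <- fnt_mutate(tree)
    expect_identical(fnt_validate(tree2), character(0))
  }
  set.seed(99)
  m1 <- fnt_mutate(tree)
  set.seed(99)
  m2 <- fnt_mutate(tree)
  expect_identical(fnt_serialize(m1), fnt_serialize(m2))
})

test_that("fitness is the label RMSE plus a parsimony penalty", {
  # net == a everywhere -> output exactly 1; all-positive labels -> RMSE 0
  one <- fnt_tree(fnt_op(c(0, 0), 0, 1, list(fnt_var(1), fnt_var(2))),
                  n_inputs = 2)
  C <- matrix(runif(8), ncol = 2)
  expect_equal(fnt_fitness(one, C, rep(1, 4)), 0)
  # constant output 1 against all-negative labels -> RMSE 1
  expect_equal(fnt_fitness(one, C, rep(0, 4)), 1)
  # parsimony adds coefficient * node_count
  expect_equal(fnt_fitness(one, C, rep(0, 4), parsimony = 1e-3), 1.003)

  # hand-computed RMSE on 4 rows
  fx <- generate_worked_fixture()
  y <- c(1, 0, 1, 0)
  rmse <- sqrt(mean((fx$outputs - y)^2))
  expect_equal(fnt_fitness(fx$tree, fx$inputs, y), rmse, tolerance = 1e-12)

  expect_error(fnt_fitness(fx$tree, fx$inputs, c(1, 0)), "rows")
})

test_that("annealing never worsens fitness and zero steps is the identity", {
  set.seed(416)
  C <- matrix(runif(60 * 9), ncol = 9)
  y <- rep(c(0, 1), 30)
  ctrl0 <- fnt_control(sa_steps_per_temp = 0)
  tree <- fnt_random_tree(9)
  expect_identical(fnt_serialize(fnt_anneal(tree, C, y, ctrl0)),
                   fnt_serialize(tree))
  ctrl <- fnt_control(sa_steps_per_temp = 5, sa_cooling = 0.8)
  for (rep in seq_len(3)) {
    tree <- fnt_random_tree(9)
    before <- fnt_fitness(tree, C, y, ctrl$parsimony_coefficient)
    after <- fnt_fitness(fnt_anneal(tree, C, y, ctrl), C, y,
                         ctrl$parsimony_coefficient)
    expect_lte(after, before + 1e-12)
  }
})

test_that("annealing preserves tree structure", {
  set.seed(417)
  C <- matrix(runif(40 * 9), ncol = 9)
  y <- rep(c(0, 1), 10)
  tree <- fnt_random_tree(9)
  out <- fnt_anneal(tree, C, y, fnt_control(sa_steps_per_temp = 5,
                                            sa_cooling = 0.7))
  strip <- function(s) gsub("w=[^ ]+ a=[^ ]+ b=[^ ]+", "", s)
  expect_identical(strip(fnt_serialize(out)), strip(fnt_serialize(tree)))
})

test_that("evolution is elitist, reproducible, and rejects degenerate labels", {
  set.seed(418)
  C <- matrix(runif(80 * 9), ncol = 9)
  y <- as.integer(C[, 1] > 0.5)
  ctrl <- tiny_evolution(seed = 7)
  res <- fnt_evolve(C, y, ctrl)
  expect_true(all(diff(res$history$best) <= 1e-12))
  expect_equal(res$best_fitness, min(res$history$best), tolerance = 1e-12)
  res2 <- fnt_evolve(C, y, ctrl)
  expect_identical(fnt_serialize(res$best_tree),
                   fnt_serialize(res2$best_tree))
  expect_error(fnt_evolve(C, rep(1, 80), ctrl), "single class")
})
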