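# Multi-grained scanning and cascade forest.

test_that("window arithmetic follows s = (m - k) + 1", {
  # m = 10, k = 4 -> 7 sub-vectors of width 4
  X <- matrix(rnorm(6 * 10), ncol = 10)
  pool <- fntstack:::window_pool(X, 4L)
  expect_identical(dim(pool), c(6L * 7L, 4L))
  # sub-instance t of sample i is the contiguous slice starting at t
  expect_identical(pool[1, ], X[1, 1:4])
  expect_identical(pool[7, ], X[1, 7:10])
  expect_identical(pool[8, ], X[2, 1:4])
})

test_that("scanned representation width is 4s per window and pairs are normalized", {
  set.seed(431)
  X <- matrix(rnorm(40 * 9), ncol = 9)
  y <- rep(c(0, 1), 20)
  scan <- mg_scan_fit(X, y, gcforest_control(window_sizes = c(3, 6),
                                             scan_trees = 5, seed = 1))
  # m = 9, windows (3, 6): s = 7 and 4, total width 4*7 + 4*4 = 44
  expect_identical(ncol(scan$representation), 44L)
  pairs <- matrix(scan$representation, ncol = 2, byrow = FALSE)
  sums <- scan$representation[, seq(1, 43, by = 2)] +
    scan$representation[, seq(2, 44, by = 2)]
  expect_true(all(abs(sums - 1) < 1e-9))
  # new-data transform has the same width
  R2 <- mg_scan_transform(scan, X[1:5, ])
  expect_identical(dim(R2), c(5L, 44L))
  expect_error(mg_scan_transform(scan, X[, 1:5]), "features")
  expect_error(mg_scan_fit(X, y, gcforest_control(window_sizes = 9)),
               "window")
})

test_that("cascade layers widen by one class-vector pair per forest", {
  set.seed(432)
  d <- generate_dataset(dataset_spec(n_pos = 40, n_neg = 40, m = 8,
                                     structure = "blobs", noise_sd = 0.5,
                                     seed = 9))
  ctrl <- gcforest_control(trees_per_forest = 20, max_layers = 4,
                           patience = 2, seed = 3)
  model <- cascade_fit(d$features, d$label, ctrl)
  expect_lte(model$n_layers_used, 4L)
  expect_gte(model$n_layers_used, 1L)
  expect_true(nzchar(model$stop_reason))
  widths <- vapply(model$layers, function(l)
    length(l$crf$forest$independent.variable.names), integer(1))
  expect_identical(widths[1], 8L)
  if (length(widths) > 1)
    expect_true(all(widths[-1] == 8L + 4L))
  probs <- cascade_predict(model, d$features)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_identical(attr(probs, "label"),
                   as.integer(probs[, 2] >= probs[, 1]))
  expect_error(cascade_fit(d$features, rep(1, 80), ctrl), "single class")
})

test_that("cascade prediction equals the average-and-argmax oracle", {
  set.seed(433)
  for (rep in seq_len(100)) {
    p1 <- runif(1)
    q1 <- runif(1)
    want <- avg_argmax(c(p1, 1 - p1), c(q1, 1 - q1))
    avg <- (c(p1, 1 - p1) + c(q1, 1 - q1)) / 2
    expect_equal(avg, want$avg)
    expect_identical(as.integer(avg[2] >= avg[1]), want$label)
  }
  # tie goes to the positive class
  expect_identical(avg_argmax(c(0.5, 0.5), c(0.5, 0.5))$label, 1L)
})

test_that("gcforest separates well-separated blobs and is deterministic", {
  d <- generate_dataset(dataset_spec(n_pos = 60, n_neg = 60, m = 12,
                                     structure = "blobs", noise_sd = 0.5,
                                     seed = 5))
  X <- d$features
  y <- d$label
  fold <- fntstack:::stratified_folds(y, 2, 7)
  tr <- fold == 1
  te <- fold == 2
  ctrl <- tiny_gcforest(seed = 2)
  fit <- gcforest_fit(X[tr, ], y[tr], ctrl)
  conf <- predict(fit, X[te, ])
  expect_true(all(conf >= 0 & conf <= 1))
  expect_gte(mean(as.integer(conf >= 0.5) == y[te]), 0.95)
  fit2 <- gcforest_fit(X[tr, ], y[tr], ctrl)
  expect_identical(predict(fit2, X[te, ]), conf)
})
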