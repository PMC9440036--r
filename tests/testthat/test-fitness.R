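test_that("binarize thresholds strictly at 0.5, clamps, and repairs", {
  expect_equal(binarize(c(0.6, 0.4, 0.51)), c(1L, 0L, 1L))
  expect_equal(binarize(c(2.0, -1.0)), c(1L, 0L))      # clamp to [1, 0]
  set.seed(1)
  rep <- binarize(c(0.5, 0.5))   # 0.5 maps to unselected -> repair fires
  expect_equal(sum(rep), 1L)
  expect_equal(binarize(c(0.3, 0.49, 0.1)), c(0L, 1L, 0L))  # largest wins
  expect_error(binarize(c(0.2, NaN)), "non-finite")
})

test_that("separated clusters give perfect KNN accuracy on one feature", {
  ds <- separable_dataset(n_per_class = 30, d = 3)
  mask <- c(1L, 0L, 0L)
  expect_equal(knn_accuracy(mask, ds, fitness_config(cv_folds = 10)), 1.0)
})

test_that("label-independent features give chance-level accuracy", {
  accs <- vapply(1:20, function(s) {
    ds <- noise_dataset(n = 200, d = 5, seed = s)
    knn_accuracy(rep(1L, 5), ds, fitness_config(seed = s))
  }, numeric(1))
  expect_true(all(accs >= 0.35 & accs <= 0.65))
})

test_that("KNN agrees with an independent classifier on a tie-free split", {
  skip_if_not_installed("caret")
  set.seed(7)
  n <- 60
  x <- matrix(runif(n * 4), n, 4)
  y <- as.integer(x[, 1] + 0.3 * rnorm(n) > 0.5)
  ds <- bdmsao_dataset(x, y, name = "crosscheck")
  cfg <- fitness_config(eval_mode = "holdout", seed = 5)
  split <- make_holdout(ds, 0.2, seed = 5)
  # replicate the fold scaling by hand, then classify with caret::knn3
  tr <- x[split$train, ]; te <- x[split$test, ]
  lo <- apply(tr, 2, min); rng <- apply(tr, 2, max) - lo
  trs <- sweep(sweep(tr, 2, lo), 2, rng, "/")
  tes <- sweep(sweep(te, 2, lo), 2, rng, "/")
  fit <- caret::knn3(trs, factor(y[split$train]), k = 5)
  pred <- as.integer(as.character(predict(fit, tes, type = "class")))
  expect_equal(knn_accuracy(rep(1L, 4), ds, cfg),
               mean(pred == y[split$test]))
})

test_that("errors: single-class data and oversized k are rejected", {
  one <- bdmsao_dataset(matrix(rnorm(20), 10, 2), rep("a", 10))
  expect_error(knn_accuracy(c(1L, 1L), one, fitness_config()),
               "single class")
  small <- separable_dataset(n_per_class = 5, d = 2)
  suppressWarnings(expect_error(   # also warns: classes smaller than k folds
    knn_accuracy(c(1L, 1L), small, fitness_config(knn_k = 9, cv_folds = 10)),
    "knn_k"))
  expect_error(knn_accuracy(c(0L, 0L, 0L), separable_dataset(),
               fitness_config()), "no features")
})

test_that("composite fitness follows the weighted error-plus-size form", {
  ds <- separable_dataset(n_per_class = 20, d = 4)
  # perfectly separable, full mask: fitness = (1 - mu) * 1 = 0.01
  full <- evaluate_fitness(rep(1L, 4), ds)
  expect_equal(full$accuracy, 1.0)
  expect_equal(full$fitness, 0.01)
  # component identity and bounds on random masks
  set.seed(2)
  nds <- noise_dataset(n = 80, d = 6)
  for (i in 1:10) {
    m <- rbinom(6, 1, 0.5); if (sum(m) == 0) m[1] <- 1L
    v <- evaluate_fitness(m, nds)
    expect_equal(v$fitness, 0.99 * (1 - v$accuracy) + 0.01 * v$d_s / 6)
    expect_gte(v$fitness, 0); expect_lte(v$fitness, 1)
    expect_equal(v$size_penalty, 0.01 * sum(m) / 6)
  }
})

test_that("fitness is monotone in accuracy and subset size", {
  # algebraic property of the composite at fixed configuration
  mu <- 0.99
  f <- function(acc, ds, D) mu * (1 - acc) + (1 - mu) * ds / D
  expect_true(f(0.9, 3, 10) > f(0.95, 3, 10))   # decreasing in accuracy
  expect_true(f(0.9, 5, 10) > f(0.9, 3, 10))    # increasing in size
  expect_equal(f(0, 10, 10), 1.0)               # worst corner
  expect_equal(f(1, 10, 10), 0.01)              # perfect, full set
})

test_that("the memoizing evaluator is transparent and counts evaluations", {
  ds <- separable_dataset(n_per_class = 15, d = 3)
  ev <- make_evaluator(ds)
  p <- c(0.7, 0.2, 0.9)
  direct <- evaluate_fitness(binarize(p), ds)
  via_pos <- ev(p)
  via_mask <- ev(binarize(p))
  expect_equal(via_pos$fitness, direct$fitness)
  expect_equal(via_pos, via_mask)
  expect_equal(attr(ev, "evals")(), 1L)         # second call was cached
  ev(c(1, 1, 1))
  expect_equal(attr(ev, "evals")(), 2L)
})

test_that("duplicated samples are classified by their own copies", {
  # every sample appears 6 times; with k = 5 the nearest neighbours of any
  # held-out point are its duplicates, so pooled CV accuracy is 1
  set.seed(3)
  base <- matrix(runif(10 * 2), 10, 2)
  y <- rep(c(0, 1), 5)
  idx <- rep(1:10, each = 6)
  ds <- bdmsao_dataset(base[idx, ], y[idx], name = "dup")
  expect_equal(knn_accuracy(c(1L, 1L), ds, fitness_config(cv_folds = 6)), 1.0)
})
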