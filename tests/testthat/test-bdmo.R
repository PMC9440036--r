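test_that("population initialization respects bounds and seeding", {
  p <- dmo_params(d = 30, n = 10, var_min = 0.4, var_max = 0.6)
  set.seed(1); pop <- init_population(p)
  expect_equal(dim(pop$positions), c(10L, 30L))
  expect_true(all(pop$positions >= 0.4 & pop$positions <= 0.6))
  set.seed(1); pop2 <- init_population(p)
  expect_identical(pop$positions, pop2$positions)
  expect_error(dmo_params(d = 5, var_min = 0.5, var_max = 0.5), "var_min")
})

test_that("alpha probabilities invert minimization and normalize", {
  expect_equal(alpha_probabilities(rep(0.3, 4)), rep(0.25, 4))
  p <- alpha_probabilities(c(0.1, 0.3))
  expect_equal(p, c(1, 0), tolerance = 1e-10)     # (0.2/0.2, 0/0.2)
  set.seed(5)
  for (i in 1:100) {
    v <- alpha_probabilities(runif(sample(2:20, 1)))
    expect_lt(abs(sum(v) - 1), 1e-12)
    expect_true(all(v >= 0))
  }
  f <- c(0.05, 0.2, 0.4)
  expect_true(all(diff(alpha_probabilities(f)) < 0))  # lower fit, higher p
  expect_error(alpha_probabilities(numeric(0)), "empty")
})

test_that("tournament selection favors the better agent 3:1 at size 2", {
  set.seed(11)
  picks <- replicate(4000, tournament_select(c(0.1, 0.9), size = 2))
  expect_equal(mean(picks == 1), 0.75, tolerance = 0.03)
  set.seed(3); a <- tournament_select(runif(10), 3)
  set.seed(3); b <- tournament_select(runif(10), 3)
  expect_identical(a, b)
  set.seed(12)                                     # size 1 = uniform draw
  u <- replicate(2000, tournament_select(c(0.1, 0.9), size = 1))
  expect_equal(mean(u == 1), 0.5, tolerance = 0.05)
})

test_that("alpha move is a peep-scaled bounded perturbation", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(alpha_move(x, peep = 2, phi = rep(0, 3)), x)
  set.seed(4)
  expect_equal(alpha_move(x, peep = 0), x)
  for (i in 1:20) {
    cand <- alpha_move(x, peep = 1.5, var_min = -10, var_max = 10)
    expect_true(all(abs(cand - x) <= 1.5))
  }
  expect_true(all(alpha_move(rep(0.5, 5), peep = 10) >= 0 &
                  alpha_move(rep(0.5, 5), peep = 10) <= 1))
})

test_that("sleeping mound normalizes the fitness change", {
  expect_equal(sleeping_mound(0.3, 0.3), 0)
  expect_equal(sleeping_mound(0.2, 0.1), 0.5)
  expect_equal(sleeping_mound(0.1, 0.2), -0.5)
  expect_equal(sleeping_mound(0, 0), 0)            # 0/0 guard
  expect_equal(average_mound(c(0.5, -0.5)), 0)
  expect_equal(average_mound(0.2), 0.2)
  expect_error(average_mound(numeric(0)), "empty")
})

test_that("CF schedule has its closed-form endpoints and is non-increasing", {
  expect_identical(compute_cf(0, 50), 1)
  expect_identical(compute_cf(50, 50), 0)
  expect_equal(compute_cf(25, 50), 0.5)
  cf <- vapply(0:100, compute_cf, numeric(1), max_iter = 100)
  expect_true(all(diff(cf) <= 1e-15))
  expect_error(compute_cf(1, 0), "positive")
})

test_that("movement vector equals the simplified broadcast of the sum", {
  set.seed(8)
  X <- matrix(runif(8 * 5, 0.1, 1), 8, 5)          # no zero coordinates
  sms <- runif(8, -1, 1)
  m <- movement_vector(X, sms)
  expect_equal(m, rep(sum(sms), 5))
  # oracle: the literal elementwise quotient form on nonzero positions
  literal <- colSums(X * sms / X)
  expect_equal(m, literal)
  expect_equal(movement_vector(matrix(1, 2, 3), c(0.5, 0.25)), rep(0.75, 3))
  expect_equal(movement_vector(X, rep(0, 8)), rep(0, 5))
  expect_equal(movement_vector(X, sms, variant = "centroid"),
               colSums(X * sms) / 8)
})

test_that("scout move degenerates to identity at its fixed points", {
  x <- c(0.3, 0.7); m <- c(0.1, 0.1)
  expect_equal(scout_move(x, cf = 0, m, 1, 0), x)
  expect_equal(scout_move(x, cf = 0.8, m, 1, 0, phi = 0), x)
  expect_equal(scout_move(m, cf = 0.8, m, 0, 1), m)          # X = M
  set.seed(9)
  for (i in 1:10)
    expect_true(all(scout_move(x, 0.9, m, i %% 2, 0.5) >= 0 &
                    scout_move(x, 0.9, m, i %% 2, 0.5) <= 1))
})

test_that("babysitter exchange refreshes the worst agents on schedule", {
  p <- dmo_params(d = 4, n = 5, n_babysitters = 2, exchange_period = 3,
                  max_iter = 10)
  set.seed(6)
  pop <- init_population(p)
  fits <- c(0.5, 0.1, 0.9, 0.7, 0.3)
  pop$fitness <- lapply(fits, function(f)
    list(fitness = f, d_s = 2L, mask = c(1L, 1L, 0L, 0L)))
  expect_identical(babysitter_exchange(pop, 2, p)$positions, pop$positions)
  out <- babysitter_exchange(pop, 3, p)
  expect_false(any(is.na(out$positions)))
  changed <- which(rowSums(out$positions != pop$positions) > 0)
  expect_setequal(changed, c(3, 4))                 # the two worst
  expect_null(out$fitness[[3]])
  expect_identical(out$fitness[[2]], pop$fitness[[2]])  # best untouched

  p0 <- dmo_params(d = 4, n = 5, n_babysitters = 0, exchange_period = 3)
  expect_identical(babysitter_exchange(pop, 3, p0), pop)

  pall <- dmo_params(d = 4, n = 5, n_babysitters = 4, exchange_period = 1)
  out2 <- babysitter_exchange(pop, 1, pall)
  expect_identical(out2$fitness[[2]], pop$fitness[[2]])
  expect_equal(sum(vapply(out2$fitness, is.null, logical(1))), 4L)
})
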