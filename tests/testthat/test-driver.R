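test_that("a degenerate budget returns the evaluated initial agent", {
  ds <- separable_dataset(n_per_class = 10, d = 4)
  dmo <- dmo_params(d = 4, n = 1, n_babysitters = 0, max_iter = 1,
                    peep = 0, seed = 21)
  res <- run_bdmsao(ds, dmo, sa_params(d = 4, max_evals = 0),
                    mode = "bdmo_only")
  # reconstruct the seeded initial agent independently
  set.seed(21)
  init <- runif(4)
  expect_equal(res$best_mask, binarize(init))
  expect_equal(res$best_fitness$fitness,
               evaluate_fitness(binarize(init), ds)$fitness)
  expect_equal(nrow(res$history), 1L)
})

test_that("history is complete, monotone, and consistent with the result", {
  gen <- make_planted(planted_spec(n_samples = 60, n_informative = 2,
                                   n_noise = 8, seed = 31))
  for (mode in c("hybrid", "bdmo_only")) {
    res <- run_bdmsao(gen$dataset,
                      dmo_params(d = 10, max_iter = 15, seed = 5),
                      mode = mode)
    expect_equal(nrow(res$history), 15L)
    expect_true(all(diff(res$history$best_fitness) <= 1e-15))
    expect_equal(res$history$best_fitness[15], res$best_fitness$fitness)
    expect_gte(sum(res$best_mask), 1L)
  }
})

test_that("runs are reproducible and respect the evaluation budget", {
  gen <- make_planted(planted_spec(n_samples = 60, n_informative = 2,
                                   n_noise = 10, seed = 32))
  dmo <- dmo_params(d = 12, n = 6, n_babysitters = 2, max_iter = 10,
                    seed = 9)
  sa <- sa_params(d = 12, max_evals = 30)
  a <- run_bdmsao(gen$dataset, dmo, sa)
  b <- run_bdmsao(gen$dataset, dmo, sa)
  expect_identical(a$best_mask, b$best_mask)
  expect_identical(a$history, b$history)
  expect_identical(a$evals, b$evals)
  # budget: init + per-iteration (alpha + scout moves for foragers, one SA
  # call, babysitter refreshes) + final SA polish
  foragers <- dmo$n - dmo$n_babysitters
  bound <- dmo$n + dmo$max_iter * (2 * foragers + sa$max_evals + dmo$n) +
    sa$max_evals
  expect_lte(a$evals, bound)
})

test_that("the per-agent 0.5 gate variant runs and stays monotone", {
  gen <- make_planted(planted_spec(n_samples = 60, n_informative = 2,
                                   n_noise = 8, seed = 33))
  res <- run_bdmsao(gen$dataset, dmo_params(d = 10, max_iter = 10, seed = 2),
                    sa_gate = "p_index")
  expect_true(all(diff(res$history$best_fitness) <= 1e-15))
  expect_gte(res$accuracy, 0.5)
})

test_that("multi_run aggregates per-run results deterministically", {
  gen <- make_planted(planted_spec(n_samples = 50, n_informative = 1,
                                   n_noise = 5, seed = 34))
  dmo <- dmo_params(d = 6, max_iter = 5)
  one <- multi_run(gen$dataset, dmo, n_runs = 1, base_seed = 4)
  single <- run_bdmsao(gen$dataset, {d <- dmo; d$seed <- 4L; d})
  expect_equal(one$mean_accuracy, single$accuracy)
  expect_equal(one$mean_n_selected, single$n_selected)

  mr <- multi_run(gen$dataset, dmo, n_runs = 3, base_seed = 7)
  expect_equal(mr$summary$seed, 7:9)
  expect_equal(mr$mean_accuracy, mean(mr$summary$accuracy))
  expect_equal(mr$mean_n_selected, mean(mr$summary$n_selected))
  mr2 <- multi_run(gen$dataset, dmo, n_runs = 3, base_seed = 7)
  expect_identical(mr$summary, mr2$summary)
  expect_identical(lapply(mr$runs, `[[`, "best_mask"),
                   lapply(mr2$runs, `[[`, "best_mask"))
})

test_that("run reports serialize to JSON with mask and history", {
  gen <- make_planted(planted_spec(n_samples = 40, n_informative = 1,
                                   n_noise = 4, seed = 35))
  res <- run_bdmsao(gen$dataset, dmo_params(d = 5, max_iter = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_run_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, res$accuracy)
  expect_equal(nchar(back$mask), 5L)
  expect_equal(length(back$history$best_fitness), 3L)
})
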