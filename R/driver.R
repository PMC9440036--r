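#' Run the hybrid BDMSAO feature-selection search
#'
#' Orchestrates the binary Dwarf Mongoose global search with the simulated
#' annealing local-search stage. Each iteration: every foraging agent
#' tournament-selects a guide and proposes a peep-scaled foraging move
#' (greedy acceptance, sleeping-mound update); in `"hybrid"` mode the
#' current best agent's mask is refined by [anneal()] (the SA stage that
#' replaces the alpha-group intensification operator); then the scout phase
#' moves every forager under the decaying CF schedule; then babysitters are
#' exchanged. After the loop a final SA polish is applied to the global
#' best. `"bdmo_only"` skips every SA call.
#'
#' The SA calls share one geometric cooling schedule across the outer loop
#' (each call advances it by up to `sa$max_evals` proposals and resumes
#' where the previous call cooled to), so over a run the local search moves
#' from exploratory high-temperature acceptance to selective
#' low-temperature refinement, continuing at the floor temperature once
#' reached; the final polish continues the same schedule.
#'
#' @param dataset A [bdmsao_dataset()].
#' @param dmo A [dmo_params()]; defaults to `dmo_params(d = n_features)`.
#' @param sa A [sa_params()]; defaults to `sa_params(d = n_features)`.
#' @param fit A [fitness_config()].
#' @param mode `"hybrid"` (default) or `"bdmo_only"`.
#' @param sa_gate `"best_agent"` (default: SA refines the iteration's best
#'   agent) or `"p_index"` (per-agent gate: agents whose mean selected-bit
#'   fraction is >= 0.5 take the foraging move, the rest take an SA
#'   refinement of their own mask).
#' @return A `bdmsao_run` list: `best_mask`, `best_fitness`
#'   (`bdmsao_fitness`), `accuracy`, `n_selected`, `selected_features`,
#'   `history` (data.frame iteration/best_fitness/best_accuracy), `seed`,
#'   `evals` (distinct classifier evaluations), `mode`.
#' @export
run_bdmsao <- function(dataset, dmo = NULL, sa = NULL,
                       fit = fitness_config(),
                       mode = c("hybrid", "bdmo_only"),
                       sa_gate = c("best_agent", "p_index")) {
  mode <- match.arg(mode)
  sa_gate <- match.arg(sa_gate)
  stopifnot(inherits(dataset, "bdmsao_dataset"))
  if (dataset$n_classes < 2L)
    stop("dataset must have at least 2 classes", call. = FALSE)
  d <- dataset$n_features
  if (is.null(dmo)) dmo <- dmo_params(d = d)
  if (is.null(sa)) sa <- sa_params(d = d)
  if (dmo$d != d) stop("dmo$d does not match the dataset", call. = FALSE)

  evaluator <- make_evaluator(dataset, fit)
  hybrid <- mode == "hybrid"

  with_seed(dmo$seed, {
    pop <- init_population(dmo)
    for (i in seq_len(dmo$n)) pop$fitness[[i]] <- evaluator(pop$positions[i, ])
    best_i <- which.min(vapply(pop$fitness, `[[`, numeric(1L), "fitness"))
    g_best <- pop$fitness[[best_i]]

    history <- data.frame(iteration = seq_len(dmo$max_iter),
                          best_fitness = NA_real_, best_accuracy = NA_real_)
    phi_prev <- 0
    sa_temp <- sa$t0                       # run-spanning cooling schedule

    for (iter in seq_len(dmo$max_iter)) {
      fit_vec <- vapply(pop$fitness, `[[`, numeric(1L), "fitness")
      foragers <- setdiff(order(fit_vec), order(fit_vec, decreasing = TRUE)[
        seq_len(dmo$n_babysitters)])

      p_index <- rowMeans(pop$positions > 0.5)
      for (i in foragers) {
        if (hybrid && sa_gate == "p_index" && p_index[i] < 0.5) {
          res <- anneal(pop$fitness[[i]]$mask, evaluator, sa,
                        t_start = sa_temp, floor = TRUE)
          sa_temp <- res$t_end
          if (better_fitness(res$fitness, pop$fitness[[i]])) {
            pop$positions[i, ] <- as.numeric(res$mask)
            pop$fitness[[i]] <- res$fitness
          }
          next
        }
        g <- if (dmo$guide_selection == "tournament") {
          foragers[tournament_select(fit_vec[foragers],
                                     min(dmo$tournament_size,
                                         length(foragers)))]
        } else {
          foragers[sample.int(length(foragers), 1L,
                              prob = alpha_probabilities(fit_vec[foragers]))]
        }
        cand <- alpha_move(pop$positions[g, ], dmo$peep, dmo$var_min,
                           dmo$var_max)
        cf_new <- evaluator(cand)
        pop$sm[i] <- sleeping_mound(cf_new$fitness, pop$fitness[[i]]$fitness)
        if (better_fitness(cf_new, pop$fitness[[i]])) {   # greedy acceptance
          pop$positions[i, ] <- cand
          pop$fitness[[i]] <- cf_new
        }
        fit_vec[i] <- pop$fitness[[i]]$fitness
      }

      if (hybrid && sa_gate == "best_agent") {
        b <- which.min(vapply(pop$fitness, `[[`, numeric(1L), "fitness"))
        res <- anneal(pop$fitness[[b]]$mask, evaluator, sa,
                      t_start = sa_temp, floor = TRUE)
        sa_temp <- res$t_end
        if (better_fitness(res$fitness, pop$fitness[[b]])) {
          pop$positions[b, ] <- as.numeric(res$mask)
          pop$fitness[[b]] <- res$fitness
        }
      }

      # scout phase
      phi_curr <- average_mound(pop$sm[foragers])
      m_vec <- movement_vector(pop$positions, pop$sm, dmo$m_variant)
      cf <- compute_cf(iter, dmo$max_iter)
      for (i in foragers) {
        cand <- scout_move(pop$positions[i, ], cf, m_vec, phi_curr, phi_prev,
                           dmo$var_min, dmo$var_max)
        cand_fit <- evaluator(cand)
        if (better_fitness(cand_fit, pop$fitness[[i]])) {
          pop$positions[i, ] <- cand
          pop$fitness[[i]] <- cand_fit
        }
      }
      phi_prev <- phi_curr

      pop <- babysitter_exchange(pop, iter, dmo)
      for (i in seq_len(dmo$n))
        if (is.null(pop$fitness[[i]]))
          pop$fitness[[i]] <- evaluator(pop$positions[i, ])

      it_best <- pop$fitness[[
        which.min(vapply(pop$fitness, `[[`, numeric(1L), "fitness"))]]
      if (better_fitness(it_best, g_best)) g_best <- it_best
      history$best_fitness[iter] <- g_best$fitness
      history$best_accuracy[iter] <- g_best$accuracy
    }

    if (hybrid) {   # final polish continues the schedule where it cooled to
      res <- anneal(g_best$mask, evaluator, sa, t_start = sa_temp,
                    floor = TRUE)
      if (better_fitness(res$fitness, g_best)) g_best <- res$fitness
      history$best_fitness[dmo$max_iter] <- g_best$fitness
      history$best_accuracy[dmo$max_iter] <- g_best$accuracy
    }
  })

  structure(
    list(best_mask = g_best$mask, best_fitness = g_best,
         accuracy = g_best$accuracy, n_selected = g_best$d_s,
         selected_features = dataset$feature_names[g_best$mask == 1L],
         history = history, seed = dmo$seed, evals = attr(evaluator, "evals")(),
         mode = mode, dataset = dataset$name),
    class = "bdmsao_run")
}

#' @export
print.bdmsao_run <- function(x, ...) {
  cat(sprintf(paste0("<bdmsao_run '%s' (%s, seed %d): accuracy %.4f, ",
                     "%d features, fitness %.6f, %d evaluations>\n"),
              x$dataset, x$mode, x$seed, x$accuracy, x$n_selected,
              x$best_fitness$fitness, x$evals))
  invisible(x)
}

#' Repeat a search over consecutive seeds and aggregate
#'
#' Runs [run_bdmsao()] with seeds `base_seed .. base_seed + n_runs - 1` and
#' reports the mean accuracy, mean selected-feature count and mean fitness
#' alongside the per-run results.
#'
#' @inheritParams run_bdmsao
#' @param n_runs Number of independent runs; default 10.
#' @param base_seed First seed.
#' @return A `bdmsao_multi_run` list: `mean_accuracy`, `mean_n_selected`,
#'   `mean_fitness`, `runs` (list of `bdmsao_run`), `summary` (data.frame).
#' @export
multi_run <- function(dataset, dmo = NULL, sa = NULL, fit = fitness_config(),
                      mode = c("hybrid", "bdmo_only"), n_runs = 10L,
                      base_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1L)
  d <- dataset$n_features
  if (is.null(dmo)) dmo <- dmo_params(d = d)
  runs <- lapply(seq_len(n_runs) - 1L, function(r) {
    dmo_r <- dmo
    dmo_r$seed <- as.integer(base_seed + r)
    run_bdmsao(dataset, dmo_r, sa, fit, mode)
  })
  summary <- data.frame(
    seed = vapply(runs, `[[`, integer(1L), "seed"),
    accuracy = vapply(runs, `[[`, numeric(1L), "accuracy"),
    n_selected = vapply(runs, `[[`, numeric(1L), "n_selected"),
    fitness = vapply(runs, function(r) r$best_fitness$fitness, numeric(1L)),
    evals = vapply(runs, `[[`, integer(1L), "evals"))
  structure(list(mean_accuracy = mean(summary$accuracy),
                 mean_n_selected = mean(summary$n_selected),
                 mean_fitness = mean(summary$fitness),
                 runs = runs, summary = summary, mode = mode,
                 base_seed = as.integer(base_seed)),
            class = "bdmsao_multi_run")
}

#' @export
print.bdmsao_multi_run <- function(x, ...) {
  cat(sprintf(paste0("<bdmsao_multi_run (%s, %d runs): mean accuracy %.4f, ",
                     "mean features %.1f, mean fitness %.6f>\n"),
              x$mode, nrow(x$summary), x$mean_accuracy, x$mean_n_selected,
              x$mean_fitness))
  invisible(x)
}

#' Serialize a run result to JSON
#'
#' @param run A `bdmsao_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "bdmsao_run"))
  obj <- list(dataset = run$dataset, mode = run$mode, seed = run$seed,
              accuracy = run$accuracy, n_selected = run$n_selected,
              fitness = run$best_fitness$fitness,
              mask = paste(run$best_mask, collapse = ""),
              selected_features = run$selected_features,
              history = run$history, evals = run$evals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
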