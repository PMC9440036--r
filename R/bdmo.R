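#' Dwarf Mongoose Optimization parameters
#'
#' Search-control parameters of the binary DMO population search. The
#' population splits into a foraging group of `n - n_babysitters` agents and
#' `n_babysitters` babysitters that sit out of the search and are refreshed
#' (re-initialized) every `exchange_period` iterations.
#'
#' @param d Problem dimension (number of features).
#' @param n Population size; default 10.
#' @param var_min,var_max Continuous position bounds; default `[0, 1]`.
#' @param max_iter Iteration budget; default 50.
#' @param peep Alpha-female vocalization scale of the foraging move
#'   `x + phi * peep`; default 2.
#' @param n_babysitters Number of babysitters `bs`; default 3.
#' @param exchange_period Iterations between babysitter exchanges; default
#'   `round(0.6 * max_iter)`.
#' @param tournament_size Tournament size for guide selection; default 2.
#' @param guide_selection `"tournament"` (default, as in the hybrid method)
#'   or `"roulette"` (fitness-proportional alpha probabilities).
#' @param m_variant Movement-vector form: `"printed"` (the sum of
#'   sleeping-mound scores broadcast over dimensions, i.e. the algebraic
#'   simplification of \eqn{\sum_i x_i\, sm_i / x_i}) or `"centroid"`
#'   (\eqn{\sum_i x_i\, sm_i / n}).
#' @param seed Integer RNG seed for the run.
#' @return A `bdmsao_dmo_params` list.
#' @export
dmo_params <- function(d, n = 10L, var_min = 0, var_max = 1, max_iter = 50L,
                       peep = 2, n_babysitters = 3L, exchange_period = NULL,
                       tournament_size = 2L,
                       guide_selection = c("tournament", "roulette"),
                       m_variant = c("printed", "centroid"), seed = 1L) {
  guide_selection <- match.arg(guide_selection)
  m_variant <- match.arg(m_variant)
  n <- as.integer(n); d <- as.integer(d); max_iter <- as.integer(max_iter)
  n_babysitters <- as.integer(n_babysitters)
  if (var_min >= var_max) stop("var_min must be < var_max", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (n_babysitters < 0L || n_babysitters >= n)
    stop("need 0 <= n_babysitters < n", call. = FALSE)
  if (is.null(exchange_period)) exchange_period <- max(1L, round(0.6 * max_iter))
  structure(list(n = n, d = d, var_min = var_min, var_max = var_max,
                 max_iter = max_iter, peep = peep,
                 n_babysitters = n_babysitters,
                 exchange_period = as.integer(exchange_period),
                 tournament_size = as.integer(tournament_size),
                 guide_selection = guide_selection, m_variant = m_variant,
                 seed = as.integer(seed)),
            class = "bdmsao_dmo_params")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Initialize the mongoose population
#'
#' Each of the `n` agents gets a position drawn i.i.d.
#' `Uniform(var_min, var_max)` in every dimension. Fitness and
#' sleeping-mound scores are unset until first evaluation.
#'
#' @param params A [dmo_params()].
#' @return List with `positions` (`n x d` matrix), `fitness` (list of
#'   `bdmsao_fitness`, initially `NULL`s), `sm` (numeric, zeros).
#' @export
init_population <- function(params) {
  pos <- matrix(stats::runif(params$n * params$d, params$var_min,
                             params$var_max),
                nrow = params$n, ncol = params$d)
  list(positions = pos, fitness = vector("list", params$n),
       sm = numeric(params$n))
}

#' Alpha-selection probabilities under minimization
#'
#' The fitness-proportional alpha probability is defined for maximization;
#' since the wrapper fitness is minimized, it is applied to the transform
#' `g_i = max(fit) - fit_i + eps`, preserving normalization while giving
#' lower (better) fitness strictly higher probability.
#'
#' @param fitnesses Finite numeric vector of fitness values (minimized).
#' @param eps Small positive constant keeping probabilities defined when all
#'   fitnesses are equal; default `1e-12`.
#' @return Probability vector summing to 1.
#' @export
alpha_probabilities <- function(fitnesses, eps = 1e-12) {
  if (length(fitnesses) == 0L) stop("empty fitness vector", call. = FALSE)
  if (any(!is.finite(fitnesses))) stop("non-finite fitness", call. = FALSE)
  g <- max(fitnesses) - fitnesses + eps
  g / sum(g)
}

#' Tournament selection of a guide agent
#'
#' Draws `size` candidates uniformly with replacement and returns the index
#' of the minimum-fitness candidate (first drawn among exact ties).
#'
#' @param fitnesses Numeric vector of agent fitness values.
#' @param size Tournament size, `1 <= size <= length(fitnesses)`.
#' @return An index into `fitnesses`.
#' @export
tournament_select <- function(fitnesses, size = 2L) {
  n <- length(fitnesses)
  if (n == 0L) stop("empty fitness vector", call. = FALSE)
  stopifnot(size >= 1L, size <= n)
  cand <- sample.int(n, size, replace = TRUE)
  cand[which.min(fitnesses[cand])]
}

#' Alpha-group foraging move
#'
#' Candidate position `x + phi * peep` with `phi ~ Uniform(-1, 1)` drawn per
#' dimension, clamped to the bounds.
#'
#' @param position Current position vector.
#' @param peep Vocalization scale.
#' @param var_min,var_max Bounds for clamping.
#' @param phi Optional fixed perturbation vector (testing hook); default
#'   drawn from the RNG.
#' @return Candidate position vector.
#' @export
alpha_move <- function(position, peep, var_min = 0, var_max = 1, phi = NULL) {
  if (is.null(phi)) phi <- stats::runif(length(position), -1, 1)
  clamp(position + phi * peep, var_min, var_max)
}

#' Sleeping-mound score
#'
#' Normalized fitness change `(fit_new - fit_old) / max(|fit_new|,
#' |fit_old|)`, defined as 0 when both operands are 0.
#'
#' @param fit_new,fit_old Scalar fitness values.
#' @return Score in `[-1, 1]` for same-sign operands.
#' @export
sleeping_mound <- function(fit_new, fit_old) {
  m <- max(abs(fit_new), abs(fit_old))
  if (m == 0) return(0)
  (fit_new - fit_old) / m
}

#' Average sleeping-mound score
#'
#' @param sms Numeric vector of sleeping-mound scores (length >= 1).
#' @return Arithmetic mean `phi`.
#' @export
average_mound <- function(sms) {
  if (length(sms) == 0L) stop("empty sleeping-mound vector", call. = FALSE)
  mean(sms)
}

#' Collective-volatile movement schedule CF
#'
#' `CF = (1 - iter/max_iter)^(2 * iter/max_iter)`: equals 1 at iteration 0,
#' decays to 0 at `max_iter`, and equals 0.5 at the midpoint.
#'
#' @param iter Current iteration, `0 <= iter <= max_iter`.
#' @param max_iter Iteration budget (> 0).
#' @return CF in `[0, 1]`.
#' @export
compute_cf <- function(iter, max_iter) {
  if (max_iter <= 0L) stop("max_iter must be positive", call. = FALSE)
  stopifnot(iter >= 0L, iter <= max_iter)
  r <- iter / max_iter
  (1 - r)^(2 * r)
}

#' Movement vector toward the next sleeping mound
#'
#' The printed form \eqn{M = \sum_i x_i\, sm_i / x_i} cancels the position
#' elementwise and reduces to the scalar \eqn{\sum_i sm_i} broadcast across
#' dimensions; that broadcast is the default. Coordinates with
#' `|x| < 1e-12` are excluded from the literal quotient, which only matters
#' for the `"centroid"` variant's sibling check. The `"centroid"` variant
#' returns the sm-weighted mean position \eqn{\sum_i x_i\, sm_i / n}.
#'
#' @param positions `n x d` matrix of agent positions.
#' @param sms Numeric vector of sleeping-mound scores, length `n`.
#' @param variant `"printed"` (default) or `"centroid"`.
#' @return Numeric vector `M` of length `d`.
#' @export
movement_vector <- function(positions, sms,
                            variant = c("printed", "centroid")) {
  variant <- match.arg(variant)
  if (variant == "printed") {
    rep(sum(sms), ncol(positions))
  } else {
    colSums(positions * sms) / nrow(positions)
  }
}

#' Scout move
#'
#' `X - CF * phi * rand * (X - M)` when the average mound score increased
#' (`phi_new > phi_old`), else `X + CF * phi * rand * (X - M)`, with
#' `phi ~ Uniform(-1, 1)` and `rand ~ Uniform(0, 1)` drawn per agent;
#' clamped to the bounds.
#'
#' @param position Current position vector.
#' @param cf Schedule value from [compute_cf()].
#' @param m Movement vector from [movement_vector()].
#' @param phi_new,phi_old Average mound scores of the current and previous
#'   iteration.
#' @param var_min,var_max Bounds.
#' @param phi,rand Optional fixed draws (testing hooks).
#' @return Candidate position vector.
#' @export
scout_move <- function(position, cf, m, phi_new, phi_old,
                       var_min = 0, var_max = 1, phi = NULL, rand = NULL) {
  if (is.null(phi)) phi <- stats::runif(1L, -1, 1)
  if (is.null(rand)) rand <- stats::runif(1L)
  step <- cf * phi * rand * (position - m)
  cand <- if (phi_new > phi_old) position - step else position + step
  clamp(cand, var_min, var_max)
}

#' Babysitter exchange
#'
#' Every `exchange_period` iterations the `n_babysitters` worst-fitness
#' agents are re-initialized uniformly within the bounds and their fitness
#' cleared for re-evaluation; the best agent is never re-initialized. All
#' other iterations are a no-op.
#'
#' @param population Population list from [init_population()] with
#'   evaluated fitness.
#' @param iter Current iteration (1-based).
#' @param params A [dmo_params()].
#' @return The (possibly updated) population list.
#' @export
babysitter_exchange <- function(population, iter, params) {
  bs <- params$n_babysitters
  if (bs == 0L || iter %% params$exchange_period != 0L) return(population)
  fit <- vapply(population$fitness, function(f) f$fitness, numeric(1L))
  worst <- order(fit, decreasing = TRUE)
  worst <- setdiff(worst, which.min(fit))[seq_len(bs)]
  for (i in worst) {
    population$positions[i, ] <- stats::runif(params$d, params$var_min,
                                              params$var_max)
    population$fitness[i] <- list(NULL)
    population$sm[i] <- 0
  }
  population
}
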