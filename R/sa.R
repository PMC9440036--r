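#' Simulated-annealing parameters
#'
#' Controls the bit-flip local search. The initial temperature follows the
#' `2 * |N|` convention with `|N|` the feature count, cooled geometrically
#' by `cooling` per level with `chain_length` proposals per level, until
#' `min_temp` is reached or `max_evals` fitness evaluations have been spent.
#'
#' @param d Feature count `|N|` (sets the default `t0`).
#' @param t0 Initial temperature; default `2 * d`.
#' @param cooling Geometric cooling factor in `(0, 1)`; default 0.93.
#' @param chain_length Proposals per temperature level; default 5.
#' @param min_temp Stopping temperature; default `1e-3 / d`: a tenth of the
#'   smallest attainable fitness difference under the default objective
#'   weight (one feature's size penalty, `(1 - 0.99) / d`), so the schedule
#'   always ends in the selective (hill-climbing) regime. A floor
#'   proportional to `t0` would leave the local search in the always-accept
#'   regime whenever `d` is large, because `t0 = 2d` grows with the
#'   dimension while the objective is bounded in `[0, 1]`.
#' @param max_evals Cap on proposals per [anneal()] call; default 100,
#'   making one call's cost independent of `d`.
#' @return A `bdmsao_sa_params` list.
#' @export
sa_params <- function(d, t0 = 2 * d, cooling = 0.93, chain_length = 5L,
                      min_temp = 1e-3 / d, max_evals = 100L) {
  if (t0 <= 0) stop("t0 must be positive", call. = FALSE)
  if (cooling <= 0 || cooling >= 1)
    stop("cooling must lie in (0, 1)", call. = FALSE)
  if (chain_length < 1L) stop("chain_length must be >= 1", call. = FALSE)
  structure(list(t0 = t0, cooling = cooling,
                 chain_length = as.integer(chain_length),
                 min_temp = min_temp, max_evals = as.integer(max_evals)),
            class = "bdmsao_sa_params")
}

#' Single-bit-flip neighbour of a feature mask
#'
#' Flips exactly one uniformly chosen bit; if the flip would empty the mask
#' it is repaired to a single random 1-bit.
#'
#' @param mask Integer 0/1 vector.
#' @param flip Optional fixed bit index (testing hook).
#' @return Neighbouring 0/1 mask.
#' @export
sa_neighbor <- function(mask, flip = NULL) {
  mask <- as.integer(mask)
  if (is.null(flip)) flip <- sample.int(length(mask), 1L)
  mask[flip] <- 1L - mask[flip]
  if (sum(mask) == 0L) mask <- repair_mask(mask)
  mask
}

#' Metropolis acceptance rule
#'
#' Improvements (`delta <= 0`) are always accepted; deteriorations with
#' probability `exp(-delta / temp)`.
#'
#' @param delta Fitness difference new minus current.
#' @param temp Current temperature (> 0).
#' @param u Optional fixed uniform draw (testing hook).
#' @return Logical: accept the candidate?
#' @export
sa_accept <- function(delta, temp, u = NULL) {
  if (temp <= 0) stop("temperature must be positive", call. = FALSE)
  if (delta <= 0) return(TRUE)
  if (is.null(u)) u <- stats::runif(1L)
  u < exp(-delta / temp)
}

#' Anneal a feature mask
#'
#' Simulated-annealing refinement of a binary feature mask: single-bit-flip
#' neighbourhood, Metropolis acceptance, geometric cooling. Elitist: the
#' best mask ever visited is tracked and returned, so the result is never
#' worse than the start.
#'
#' @param start Integer 0/1 starting mask (at least one 1-bit).
#' @param evaluator Function mask -> `bdmsao_fitness` list (typically from
#'   [make_evaluator()], whose memoization makes revisited masks free).
#' @param params A [sa_params()].
#' @param t_start Optional temperature to resume from (used by the driver to
#'   spread one cooling schedule across outer iterations); default
#'   `params$t0`.
#' @param floor Logical: if `TRUE`, once the schedule reaches `min_temp` the
#'   chain keeps proposing at that temperature (hill-climbing regime) until
#'   `max_evals` is exhausted, instead of stopping. Used by the driver so
#'   late-run refinement continues after the shared schedule has cooled.
#' @return List: `mask` (best visited), `fitness` (its `bdmsao_fitness`),
#'   `evals` (proposals evaluated), `t_end` (temperature reached).
#' @export
anneal <- function(start, evaluator, params, t_start = NULL, floor = FALSE) {
  current_mask <- as.integer(start)
  current <- evaluator(current_mask)
  best_mask <- current_mask
  best <- current
  temp <- if (is.null(t_start)) params$t0 else t_start
  if (floor) temp <- max(temp, params$min_temp)
  evals <- 0L
  while ((floor || temp > params$min_temp) && evals < params$max_evals) {
    for (j in seq_len(params$chain_length)) {
      if (evals >= params$max_evals) break
      cand_mask <- sa_neighbor(current_mask)
      cand <- evaluator(cand_mask)
      evals <- evals + 1L
      if (better_fitness(cand, best)) {   # elitist: best ever visited
        best_mask <- cand_mask
        best <- cand
      }
      if (sa_accept(cand$fitness - current$fitness, temp)) {
        current_mask <- cand_mask
        current <- cand
      }
    }
    temp <- temp * params$cooling
    if (floor) temp <- max(temp, params$min_temp)
  }
  list(mask = best_mask, fitness = best, evals = evals, t_end = temp)
}
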