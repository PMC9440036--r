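#' Friedman mean ranks of algorithm accuracies
#'
#' Ranks algorithms within each run by accuracy, the best algorithm
#' receiving the highest rank number (so larger mean rank = better, the
#' convention used when reporting wrapper-selection benchmarks); ties get
#' average ranks. Returns the per-algorithm column means.
#'
#' @param accuracy_table Numeric matrix, runs in rows, algorithms in
#'   columns (>= 2 of each).
#' @return Named numeric vector of mean ranks, one per algorithm.
#' @export
friedman_mean_ranks <- function(accuracy_table) {
  accuracy_table <- as.matrix(accuracy_table)
  if (nrow(accuracy_table) < 2L || ncol(accuracy_table) < 2L)
    stop("need at least 2 runs and 2 algorithms", call. = FALSE)
  if (anyNA(accuracy_table))
    stop("accuracy table contains missing values", call. = FALSE)
  ranks <- t(apply(accuracy_table, 1L, rank, ties.method = "average"))
  colMeans(ranks)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired accuracy vectors: exact for
#' up to 25 nonzero differences (without ties in their magnitudes), normal
#' approximation with continuity correction otherwise. All-zero differences
#' are reported as `p = 1` with `degenerate = TRUE`.
#'
#' @param paired_a,paired_b Equal-length numeric vectors of paired results.
#' @param alpha Significance threshold reported alongside; default 0.05.
#' @return List: `p_value`, `statistic` (V), `significant`, `degenerate`,
#'   `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, alpha = 0.05) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length", call. = FALSE)
  diffs <- paired_a - paired_b
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L)
    return(list(p_value = 1, statistic = NA_real_, significant = FALSE,
                degenerate = TRUE, n_nonzero = 0L))
  if (length(nz) < 5L)
    stop("need >= 5 nonzero differences", call. = FALSE)
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  ht <- suppressWarnings(
    stats::wilcox.test(paired_a, paired_b, paired = TRUE, exact = exact,
                       correct = TRUE))
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       significant = ht$p.value < alpha, degenerate = FALSE,
       n_nonzero = length(nz))
}

#' Run a benchmark experiment and write report files
#'
#' Executes [multi_run()] for every dataset and mode in the configuration
#' and writes `summary.csv` (one row per dataset x mode with mean accuracy
#' as a percentage and mean selected-feature count), per-run JSON files and
#' a per-run convergence CSV (iteration, best fitness, best accuracy) into
#' the output directory, which is created if missing.
#'
#' @param datasets Named list of [bdmsao_dataset()] objects.
#' @param modes Character vector of modes, subset of
#'   `c("hybrid", "bdmo_only")`.
#' @param out_dir Output directory.
#' @param n_runs Runs per dataset x mode; default 10.
#' @param base_seed First seed; default 1.
#' @param dmo,sa,fit Optional parameter objects passed through (defaults
#'   derived per dataset).
#' @return Data frame of the summary table, invisibly; files are written as
#'   a side effect.
#' @export
run_experiment <- function(datasets, modes = c("hybrid", "bdmo_only"),
                           out_dir = "bdmsao_results", n_runs = 10L,
                           base_seed = 1L, dmo = NULL, sa = NULL,
                           fit = fitness_config()) {
  stopifnot(is.list(datasets), length(datasets) > 0L)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, character(1L), "name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  conv <- list()
  t0 <- Sys.time()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (mode in modes) {
      mr <- multi_run(ds, dmo = dmo, sa = sa, fit = fit, mode = mode,
                      n_runs = n_runs, base_seed = base_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds_name, mode = mode, n_runs = n_runs,
        mean_accuracy_pct = round(100 * mr$mean_accuracy, 2L),
        mean_n_selected = mr$mean_n_selected,
        mean_fitness = mr$mean_fitness)
      for (run in mr$runs) {
        write_run_json(run, file.path(out_dir,
          sprintf("run_%s_%s_seed%d.json", ds_name, mode, run$seed)))
        h <- run$history
        h$dataset <- ds_name; h$mode <- mode; h$seed <- run$seed
        conv[[length(conv) + 1L]] <- h
      }
    }
  }
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, conv),
                   file.path(out_dir, "convergence.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(base_seed = base_seed, n_runs = n_runs, modes = modes,
         version = as.character(utils::packageVersion("bdmsao")),
         elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(out_dir, "meta.json"), auto_unbox = TRUE)
  invisible(summary)
}
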