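#' Specification for a planted-feature dataset
#'
#' Describes a synthetic classification problem with a known informative
#' subset: informative features are class-conditional Gaussians whose class
#' means are `class_sep` standard deviations apart; noise features are
#' class-independent standard Gaussians. Defaults mirror a mid-size tabular
#' benchmark: 100 samples, 5 informative + 45 noise features, 2 classes,
#' separation 4.
#'
#' @param n_samples Number of samples; default 100.
#' @param n_informative Number of informative features (>= 1); default 5.
#' @param n_noise Number of noise features; default 45.
#' @param n_classes Number of classes (>= 2); default 2.
#' @param class_sep Separation between adjacent class means in units of the
#'   within-class standard deviation; default 4.
#' @param label_noise Fraction of labels flipped uniformly at random, in
#'   `[0, 0.5)`; default 0.
#' @param seed Integer RNG seed.
#' @return A `bdmsao_planted_spec` list.
#' @export
planted_spec <- function(n_samples = 100L, n_informative = 5L, n_noise = 45L,
                         n_classes = 2L, class_sep = 4, label_noise = 0,
                         seed = 1L) {
  if (n_informative < 1L) stop("n_informative must be >= 1", call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_classes = as.integer(n_classes), class_sep = class_sep,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "bdmsao_planted_spec")
}

#' Generate a planted-feature dataset
#'
#' Labels are assigned in balanced round-robin order and shuffled.
#' Informative feature `j` for class `c` is drawn `N(c * class_sep, 1)`;
#' noise features are `N(0, 1)` regardless of class. Informative columns
#' are placed at random positions among the noise columns.
#'
#' @param spec A [planted_spec()].
#' @return List with `dataset` (a [bdmsao_dataset()]) and `informative`
#'   (integer indices of the planted features).
#' @export
make_planted <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "bdmsao_planted_spec"))
  d <- spec$n_informative + spec$n_noise
  with_seed(spec$seed, {
    y <- sample((seq_len(spec$n_samples) - 1L) %% spec$n_classes)
    x <- matrix(stats::rnorm(spec$n_samples * d), spec$n_samples, d)
    info <- sort(sample.int(d, spec$n_informative))
    for (j in info) x[, j] <- x[, j] + y * spec$class_sep
    if (spec$label_noise > 0) {
      n_flip <- round(spec$label_noise * spec$n_samples)
      flip <- sample.int(spec$n_samples, n_flip)
      y[flip] <- (y[flip] + sample.int(spec$n_classes - 1L, n_flip,
                                       replace = TRUE)) %% spec$n_classes
    }
  })
  ds <- bdmsao_dataset(x, y, paste0("f", seq_len(d)),
                       name = sprintf("planted_%dx%d_s%d", spec$n_samples, d,
                                      spec$seed))
  list(dataset = ds, informative = info)
}

#' Generate an expression-style high-dimensional dataset
#'
#' Emulates the shape of microarray gene-expression benchmarks (tens of
#' samples, thousands of positive-valued features, two classes): a planted
#' Gaussian design in log space, exponentiated so values are positive with
#' a log-normal-like right skew. Only shape and separability are emulated,
#' not real microarray covariance structure.
#'
#' @param n_samples Number of samples (e.g. 62).
#' @param n_features Total feature count (e.g. 2000).
#' @param n_informative Number of planted informative features.
#' @param class_sep Log-space class-mean separation in within-class SDs;
#'   default 6.
#' @param n_classes Number of classes; default 2.
#' @param seed Integer RNG seed.
#' @return List with `dataset` and `informative`, as [make_planted()].
#' @export
make_expression_like <- function(n_samples, n_features, n_informative,
                                 class_sep = 6, n_classes = 2L, seed = 1L) {
  if (n_features < n_informative)
    stop("n_features must be >= n_informative", call. = FALSE)
  spec <- planted_spec(n_samples, n_informative,
                       n_noise = n_features - n_informative,
                       n_classes = n_classes, class_sep = class_sep,
                       seed = seed)
  gen <- make_planted(spec)
  feats <- exp(gen$dataset$features)       # log-normal-like positive values
  ds <- bdmsao_dataset(feats, gen$dataset$labels,
                       paste0("g", seq_len(n_features)),
                       name = sprintf("expr_%dx%d_s%d", n_samples,
                                      n_features, seed))
  list(dataset = ds, informative = gen$informative)
}

#' Exhaustive feature-subset oracle
#'
#' Evaluates every nonempty feature subset (all `2^D - 1` masks) with the
#' identical evaluator and tie-breaking used by the search, returning the
#' global optimum. Refuses dimensions above `max_dim` (the subset count is
#' exponential).
#'
#' @param dataset A [bdmsao_dataset()] with at most `max_dim` features.
#' @param fit A [fitness_config()].
#' @param max_dim Combinatorial guard; default 20.
#' @return List: `mask` (optimal 0/1 vector), `fitness` (its
#'   `bdmsao_fitness`), `n_evaluated`.
#' @export
exhaustive_oracle <- function(dataset, fit = fitness_config(),
                              max_dim = 20L) {
  stopifnot(inherits(dataset, "bdmsao_dataset"))
  d <- dataset$n_features
  if (d > max_dim)
    stop("refusing exhaustive search over ", d, " features (max_dim = ",
         max_dim, ")", call. = FALSE)
  evaluator <- make_evaluator(dataset, fit)
  best <- NULL
  best_mask <- NULL
  for (code in seq_len(2^d - 1)) {
    mask <- as.integer(intToBits(code)[seq_len(d)])
    val <- evaluator(mask)
    if (is.null(best) || better_fitness(val, best)) {
      best <- val
      best_mask <- mask
    }
  }
  list(mask = best_mask, fitness = best, n_evaluated = 2^d - 1)
}
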