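#' Wrapper-fitness configuration
#'
#' Parameters of the composite minimization objective
#' \deqn{f = \mu (1 - A_c) + (1 - \mu)\, d_s / D_t,}
#' where \eqn{A_c} is the KNN classification accuracy of the candidate
#' subset, \eqn{d_s} its size, and \eqn{D_t} the total feature count. With
#' the default \eqn{\mu = 0.99} the error term dominates and the size term
#' acts as a tie-breaker favouring small subsets.
#'
#' @param mu Weight on the classification error, in `[0, 1]`; default 0.99.
#' @param knn_k Neighbour count for the KNN classifier; default 5.
#' @param cv_folds Cross-validation fold count; default 10.
#' @param eval_mode `"cv"` (pooled k-fold CV accuracy, default) or
#'   `"holdout"` (stratified 80/20 split).
#' @param seed Integer seed controlling fold/split construction.
#' @return A `bdmsao_fitness_config` list.
#' @export
fitness_config <- function(mu = 0.99, knn_k = 5L, cv_folds = 10L,
                           eval_mode = c("cv", "holdout"), seed = 1L) {
  eval_mode <- match.arg(eval_mode)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(mu = mu, knn_k = as.integer(knn_k),
                 cv_folds = as.integer(cv_folds), eval_mode = eval_mode,
                 seed = as.integer(seed)),
            class = "bdmsao_fitness_config")
}

#' Binarize a continuous position into a feature mask
#'
#' Positions are clamped to `[0, 1]`; bit `j` is 1 iff the clamped position
#' exceeds 0.5 (strictly). If that leaves no feature selected, the mask is
#' repaired by switching on the bit with the largest continuous position
#' (random among ties), since the wrapper objective is undefined for an
#' empty subset.
#'
#' @param position Finite numeric vector.
#' @return Integer 0/1 vector of the same length with at least one 1-bit.
#' @export
binarize <- function(position) {
  if (any(!is.finite(position)))
    stop("position contains non-finite entries", call. = FALSE)
  p <- pmin(pmax(position, 0), 1)
  bits <- as.integer(p > 0.5)
  if (sum(bits) == 0L) bits <- repair_mask(bits, p)
  bits
}

# Empty-mask repair: set the bit with the largest continuous score; a pure
# (all-equal) score vector gets a uniformly random bit.
repair_mask <- function(bits, scores = NULL) {
  if (is.null(scores)) scores <- rep(1, length(bits))
  top <- which(scores == max(scores))
  pick <- if (length(top) > 1L) top[sample.int(length(top), 1L)] else top
  bits[pick] <- 1L
  bits
}

# Precompute per-fold min-max-scaled train/test matrices. Scaling parameters
# come from the training portion only and are mask-independent, so this is
# done once per dataset/config, not per evaluation.
scaled_folds <- function(dataset, config) {
  if (dataset$n_classes < 2L)
    stop("dataset has a single class; accuracy is undefined", call. = FALSE)
  splits <- if (config$eval_mode == "cv") {
    plan <- make_folds(dataset, config$cv_folds, config$seed)
    lapply(seq_len(plan$k) - 1L, function(f) {
      te <- which(plan$assignments == f)
      list(train = setdiff(seq_len(dataset$n_samples), te), test = te)
    })
  } else {
    list(make_holdout(dataset, 0.2, config$seed))
  }
  lapply(splits, function(s) {
    tr <- dataset$features[s$train, , drop = FALSE]
    te <- dataset$features[s$test, , drop = FALSE]
    if (config$knn_k >= nrow(tr))
      stop("knn_k (", config$knn_k, ") must be smaller than the training ",
           "set (", nrow(tr), ")", call. = FALSE)
    lo <- apply(tr, 2L, min)
    hi <- apply(tr, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1            # constant feature: maps to 0, harmless
    tr <- sweep(sweep(tr, 2L, lo), 2L, rng, "/")
    te <- sweep(sweep(te, 2L, lo), 2L, rng, "/")
    list(tr = tr, ytr = dataset$labels[s$train],
         te = te, yte = dataset$labels[s$test])
  })
}

#' KNN wrapper accuracy of a feature subset
#'
#' Fraction of correctly classified evaluation samples using a Euclidean
#' k-nearest-neighbour classifier restricted to the selected features. In
#' `"cv"` mode predictions are pooled over all folds; features are min-max
#' scaled to `[0, 1]` on each training portion (parameters applied to the
#' held-out portion). Deterministic for fixed seed and inputs: neighbour
#' ties are broken by smallest training index, vote ties by the nearest
#' tied class.
#'
#' @param mask Integer/logical 0/1 vector of length `n_features`.
#' @param dataset A [bdmsao_dataset()].
#' @param config A [fitness_config()].
#' @param folds Optional precomputed result of the internal fold scaler,
#'   reused by the evaluator cache.
#' @return Accuracy in `[0, 1]`.
#' @export
knn_accuracy <- function(mask, dataset, config = fitness_config(),
                         folds = NULL) {
  mask <- as.integer(mask)
  if (sum(mask) < 1L) stop("mask selects no features", call. = FALSE)
  if (is.null(folds)) folds <- scaled_folds(dataset, config)
  sel <- which(mask == 1L) - 1L
  ct <- .cpp_cv_knn_correct(folds, sel, config$knn_k, dataset$n_classes)
  ct[1L] / ct[2L]
}

#' Evaluate the composite fitness of a position or mask
#'
#' Applies [binarize()] when given a continuous position, computes the KNN
#' wrapper accuracy of the resulting subset and returns the composite
#' minimization fitness together with its components.
#'
#' @inheritParams knn_accuracy
#' @param position_or_mask Continuous position vector or 0/1 mask.
#' @return A `bdmsao_fitness` list: `fitness`, `accuracy`, `size_penalty`,
#'   `d_s`, `mask`.
#' @export
evaluate_fitness <- function(position_or_mask, dataset,
                             config = fitness_config(), folds = NULL) {
  x <- as.numeric(position_or_mask)
  mask <- if (all(x %in% c(0, 1)) && sum(x) >= 1) as.integer(x) else
    binarize(x)
  acc <- knn_accuracy(mask, dataset, config, folds)
  d_s <- sum(mask)
  pen <- (1 - config$mu) * d_s / dataset$n_features
  structure(list(fitness = config$mu * (1 - acc) + pen, accuracy = acc,
                 size_penalty = pen, d_s = d_s, mask = mask),
            class = "bdmsao_fitness")
}

#' Build a memoizing fitness evaluator
#'
#' Returns a closure `f(position_or_mask)` equivalent to
#' [evaluate_fitness()] but with the fold scaling precomputed once and the
#' result memoized by mask bits — identical masks are classified only once
#' per run, which is where the search spends its budget. The closure carries
#' an evaluation counter: `attr(f, "evals")()` returns the number of
#' distinct (non-cached) classifier evaluations performed.
#'
#' @inheritParams knn_accuracy
#' @return A function of one argument returning a `bdmsao_fitness` list.
#' @export
make_evaluator <- function(dataset, config = fitness_config()) {
  folds <- scaled_folds(dataset, config)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n_evals <- 0L
  f <- function(position_or_mask) {
    x <- as.numeric(position_or_mask)
    mask <- if (all(x %in% c(0, 1)) && sum(x) >= 1) as.integer(x) else
      binarize(x)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- evaluate_fitness(mask, dataset, config, folds)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }
  attr(f, "evals") <- function() n_evals
  f
}

# Deterministic preference order on fitness values: lower fitness, then
# fewer selected features, then lexicographically smaller bit vector.
better_fitness <- function(a, b) {
  if (a$fitness != b$fitness) return(a$fitness < b$fitness)
  if (a$d_s != b$d_s) return(a$d_s < b$d_s)
  cmp <- which(a$mask != b$mask)
  length(cmp) > 0L && a$mask[cmp[1L]] < b$mask[cmp[1L]]
}
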