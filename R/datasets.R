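#' Construct a classification dataset
#'
#' The basic container used throughout the package: a numeric feature matrix
#' with one integer class label per sample. Labels are stored as contiguous
#' integers `0..C-1`; the mapping from original label values is kept in
#' `label_levels` (first-appearance order).
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#' @param labels Vector of class labels, one per row of `features`. Recoded
#'   to integers `0..C-1` in first-appearance order.
#' @param feature_names Optional character vector of feature names; defaults
#'   to the column names of `features` or `V1..Vd`.
#' @param name Identifier string for reports.
#' @return An object of class `bdmsao_dataset` with elements `features`
#'   (matrix), `labels` (integer vector), `feature_names`, `label_levels`,
#'   `name`, `n_samples`, `n_features`, `n_classes`.
#' @export
bdmsao_dataset <- function(features, labels, feature_names = NULL,
                           name = "dataset") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 2L)
    stop("dataset must contain at least 2 samples", call. = FALSE)
  if (ncol(features) < 1L)
    stop("dataset must contain at least 1 feature", call. = FALSE)
  if (length(labels) != nrow(features))
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(features), ")", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names))
      feature_names <- paste0("V", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features))
    stop("feature_names length != number of features", call. = FALSE)
  levels <- unique(as.character(labels))          # first-appearance order
  y <- match(as.character(labels), levels) - 1L
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = y, feature_names = feature_names,
         label_levels = levels, name = name,
         n_samples = nrow(features), n_features = ncol(features),
         n_classes = length(levels)),
    class = "bdmsao_dataset")
}

#' @export
print.bdmsao_dataset <- function(x, ...) {
  cat(sprintf("<bdmsao_dataset '%s': %d samples x %d features, %d classes>\n",
              x$name, x$n_samples, x$n_features, x$n_classes))
  invisible(x)
}

#' Read a CSV classification dataset
#'
#' Reads an RFC-4180-style CSV with a header row. One column holds the class
#' label (by name or 0-based index); all other columns must be numeric.
#' Labels are encoded as contiguous integers in first-appearance order, so
#' the encoding is stable under column reordering.
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the label column, or its 0-based index.
#' @param delimiter Field delimiter, default `","`.
#' @param name Dataset identifier; defaults to the file name.
#' @return A [bdmsao_dataset()].
#' @export
read_csv_dataset <- function(path, label_column = "label", delimiter = ",",
                             name = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        stringsAsFactors = FALSE, colClasses = "character")
  if (is.numeric(label_column)) {
    idx <- as.integer(label_column) + 1L     # 0-based index contract
    if (idx < 1L || idx > ncol(df))
      stop("label column index ", label_column, " out of range", call. = FALSE)
  } else {
    idx <- match(label_column, names(df))
    if (is.na(idx))
      stop("label column '", label_column, "' not found in header",
           call. = FALSE)
  }
  labels <- df[[idx]]
  feat_df <- df[-idx]
  feats <- matrix(NA_real_, nrow(df), ncol(feat_df))
  for (j in seq_along(feat_df)) {
    v <- suppressWarnings(as.numeric(feat_df[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   feat_df[[j]][bad[1L]], bad[1L], names(feat_df)[j]),
           call. = FALSE)
    feats[, j] <- v
  }
  colnames(feats) <- names(feat_df)
  bdmsao_dataset(feats, labels, names(feat_df),
                 name = if (is.null(name)) basename(path) else name)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_csv_dataset()]: features are written with 17 significant
#' digits so a write/read round trip reproduces the matrix bit-identically,
#' and labels are written as the original label values so re-reading yields
#' the same integer encoding.
#'
#' @param dataset A [bdmsao_dataset()].
#' @param path Output path.
#' @param label_column Header name for the label column.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(dataset, path, label_column = "label",
                              delimiter = ",") {
  stopifnot(inherits(dataset, "bdmsao_dataset"))
  cols <- lapply(seq_len(dataset$n_features), function(j)
    sprintf("%.17g", dataset$features[, j]))
  names(cols) <- dataset$feature_names
  cols[[label_column]] <- dataset$label_levels[dataset$labels + 1L]
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ARFF classification dataset
#'
#' Standard `@relation`/`@attribute`/`@data` dialect via
#' [foreign::read.arff()]. The class attribute defaults to the last nominal
#' attribute; any other nominal attribute is rejected rather than silently
#' one-hot expanded (which would change the feature-count denominator of the
#' fitness function).
#'
#' @param path Path to the ARFF file.
#' @param class_attribute Optional class attribute name; default = the last
#'   nominal attribute.
#' @return A [bdmsao_dataset()].
#' @export
read_arff_dataset <- function(path, class_attribute = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- foreign::read.arff(path)
  nominal <- vapply(df, function(x) is.factor(x) || is.character(x),
                    logical(1L))
  if (is.null(class_attribute)) {
    if (!any(nominal))
      stop("no nominal attribute found to use as class", call. = FALSE)
    class_attribute <- names(df)[max(which(nominal))]
  }
  idx <- match(class_attribute, names(df))
  if (is.na(idx))
    stop("class attribute '", class_attribute, "' not found", call. = FALSE)
  other_nominal <- setdiff(names(df)[nominal], class_attribute)
  if (length(other_nominal) > 0L)
    stop("nominal non-class attributes are not supported: ",
         paste(other_nominal, collapse = ", "), call. = FALSE)
  labels <- as.character(df[[idx]])
  feats <- as.matrix(df[-idx])
  bdmsao_dataset(feats, labels, names(df)[-idx], name = basename(path))
}

#' Build a k-fold cross-validation plan
#'
#' Deterministic (per seed) fold assignment, stratified by class by default
#' so per-fold class proportions stay within one sample of the global
#' proportions. If any class has fewer than `k` members, stratification falls
#' back to plain shuffled folds with a warning.
#'
#' @param dataset A [bdmsao_dataset()].
#' @param k Number of folds (>= 2), default 10.
#' @param seed Integer RNG seed.
#' @param stratified Stratify by class? Default `TRUE`.
#' @return An object of class `bdmsao_foldplan`: list with `k`,
#'   `assignments` (fold index `0..k-1` per sample), `seed`, `stratified`.
#' @export
make_folds <- function(dataset, k = 10L, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(dataset, "bdmsao_dataset"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- dataset$n_samples
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")",
                  call. = FALSE)
  counts <- tabulate(dataset$labels + 1L, nbins = dataset$n_classes)
  if (stratified && any(counts < k)) {
    warning("some class has fewer than k samples; using unstratified folds",
            call. = FALSE)
    stratified <- FALSE
  }
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (c in seq_len(dataset$n_classes) - 1L) {
        idx <- which(dataset$labels == c)
        idx <- idx[sample.int(length(idx))]
        assignments[idx] <- (seq_along(idx) - 1L) %% k
      }
      # rotate fold ids so fold sizes stay balanced across classes
    } else {
      idx <- sample.int(n)
      assignments[idx] <- (seq_len(n) - 1L) %% k
    }
  })
  structure(list(k = k, assignments = assignments, seed = as.integer(seed),
                 stratified = stratified),
            class = "bdmsao_foldplan")
}

#' Stratified holdout split
#'
#' @param dataset A [bdmsao_dataset()].
#' @param test_fraction Fraction of samples held out for evaluation.
#' @param seed Integer RNG seed.
#' @return List with integer vectors `train` and `test` (1-based row indices).
#' @export
make_holdout <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "bdmsao_dataset"),
            test_fraction > 0, test_fraction < 1)
  test <- integer(0)
  with_seed(seed, {
    for (c in seq_len(dataset$n_classes) - 1L) {
      idx <- which(dataset$labels == c)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, idx[sample.int(length(idx), n_test)])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(dataset$n_samples), test), test = test)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  env <- parent.frame()
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  eval(substitute(code), env)
}
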