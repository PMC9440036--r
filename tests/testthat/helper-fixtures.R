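# Shared fixtures, all built in code at test time.

# Tiny 4x3 CSV: two numeric features plus a string label column.
write_tiny_csv <- function(path, label_first = FALSE, delimiter = ",") {
  header <- c("x1", "x2", "label")
  rows <- list(c("1.5", "2.0", "A"), c("1.0", "2.5", "A"),
               c("3.5", "0.5", "B"), c("4.0", "1.0", "B"))
  if (label_first) {
    header <- header[c(3, 1, 2)]
    rows <- lapply(rows, function(r) r[c(3, 1, 2)])
  }
  writeLines(c(paste(header, collapse = delimiter),
               vapply(rows, paste, character(1), collapse = delimiter)),
             path)
  path
}

# Two classes, tight clusters far apart on every feature: any nonempty
# subset classifies perfectly with KNN.
separable_dataset <- function(n_per_class = 20, d = 3, gap = 100, seed = 1) {
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * d, 0, 0.1), n_per_class, d)
  x1 <- matrix(rnorm(n_per_class * d, gap, 0.1), n_per_class, d)
  bdmsao_dataset(rbind(x0, x1), rep(c(0, 1), each = n_per_class),
                 name = "separable")
}

# Labels independent of all features.
noise_dataset <- function(n = 200, d = 5, seed = 1) {
  set.seed(seed)
  bdmsao_dataset(matrix(rnorm(n * d), n, d), rep(c(0, 1), n / 2),
                 name = "noise")
}

# Fitness evaluator stub counting 1-bits, shaped like a bdmsao_fitness.
bitcount_evaluator <- function(mask) {
  mask <- as.integer(mask)
  list(fitness = sum(mask), accuracy = NA_real_, size_penalty = NA_real_,
       d_s = sum(mask), mask = mask)
}
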