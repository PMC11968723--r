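#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
NULL

# logistic transfer used for position -> mask binarization
sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# vectorized column standard deviations (denominator n - 1)
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(0, (colSums(x^2) - n * mu^2) / (n - 1)))
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * k) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (open) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (open) "(" else "[", format(lower), format(upper),
      if (open) ")" else "]", x
    ))
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

# Split a data frame holding one class column into an expression matrix and
# a factor of labels; every non-class column must be numeric.
split_dataset <- function(data, class_col = "class") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!class_col %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", class_col))
  }
  y <- data[[class_col]]
  if (!is.factor(y)) y <- factor(y)
  x <- data[setdiff(names(data), class_col)]
  not_num <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf(
      "Non-numeric gene columns: %s.",
      paste(utils::head(not_num, 5), collapse = ", ")
    ))
  }
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) abort("`data` contains missing values.")
  if (nlevels(droplevels(y)) < 2) abort("`data` must contain at least 2 classes.")
  list(x = x, y = droplevels(y))
}

# Stratified fold assignment: within each class, members are shuffled and
# dealt round-robin into k folds.
make_folds <- function(y, k, seed = NULL) {
  y <- as.factor(y)
  smallest <- min(table(y))
  if (smallest < k) {
    warn(sprintf(
      "Smallest class has %d members; reducing folds from %d to %d.",
      smallest, k, smallest
    ))
    k <- smallest
  }
  if (k < 2) abort("Cannot build fewer than 2 cross-validation folds.")
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
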