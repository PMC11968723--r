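#' Configure the gene-subset fitness function
#'
#' The composite fitness of a gene subset `s` is
#' `f(s) = alpha * A + (1 - alpha) * (1 - Ns/Nt) - W * P(s)`,
#' where `A` is the inner cross-validated accuracy of the wrapped classifier
#' on the selected genes, `Ns/Nt` the selected fraction (so the middle term
#' rewards sparsity), and `P(s)` the mean absolute pairwise correlation of
#' the selected genes (penalizing redundant subsets). `alpha` close to 1
#' makes accuracy dominate.
#'
#' @param alpha_weight Accuracy/sparsity trade-off in `[0, 1]` (default 0.9:
#'   accuracy-dominated).
#' @param redundancy_weight Weight `W >= 0` of the redundancy penalty
#'   (default 0.1).
#' @param transfer_threshold Sigmoid threshold for binarizing continuous
#'   positions into masks (default 0.5, i.e. positive position = selected).
#' @param inner_cv_folds Stratified folds of the inner accuracy estimate
#'   (default 5).
#' @param mutation_rate_max,mutation_rate_min Endpoints of the linearly
#'   decaying per-bit mutation rate (defaults 0.1 and 0.01).
#' @param cor_method Correlation used by the redundancy penalty:
#'   `"pearson"` (default) or `"spearman"`.
#' @return An object of class `fitness_config`.
#' @examples
#' fitness_config(alpha_weight = 0.95)
#' @export
fitness_config <- function(alpha_weight = 0.9, redundancy_weight = 0.1,
                           transfer_threshold = 0.5, inner_cv_folds = 5,
                           mutation_rate_max = 0.1, mutation_rate_min = 0.01,
                           cor_method = c("pearson", "spearman")) {
  check_number(alpha_weight, "alpha_weight", 0, 1)
  check_number(redundancy_weight, "redundancy_weight", lower = 0)
  check_number(transfer_threshold, "transfer_threshold", 0, 1, open = TRUE)
  check_number(inner_cv_folds, "inner_cv_folds", lower = 2, integer = TRUE)
  check_number(mutation_rate_max, "mutation_rate_max", 0, 1)
  check_number(mutation_rate_min, "mutation_rate_min", 0, 1)
  if (mutation_rate_min > mutation_rate_max) {
    abort("`mutation_rate_min` must not exceed `mutation_rate_max`.")
  }
  structure(
    list(alpha_weight = alpha_weight, redundancy_weight = redundancy_weight,
         transfer_threshold = transfer_threshold,
         inner_cv_folds = as.integer(inner_cv_folds),
         mutation_rate_max = mutation_rate_max,
         mutation_rate_min = mutation_rate_min,
         cor_method = match.arg(cor_method)),
    class = "fitness_config"
  )
}

#' Binarize a continuous position into a gene mask
#'
#' Gene `j` is selected iff `sigmoid(position_j) > threshold` (strictly
#' greater, so a position of exactly 0 at the default threshold is not
#' selected). If no gene passes, the repair rule selects the single gene
#' with the largest position, so a mask is never empty.
#'
#' @param position Finite numeric vector of optimizer positions.
#' @param threshold Sigmoid-scale threshold in (0, 1), default 0.5.
#' @return A logical vector of the same length with at least one `TRUE`.
#' @examples
#' binarize(c(-1, 0, 1))
#' binarize(c(-3, -2, -1)) # argmax repair
#' @export
binarize <- function(position, threshold = 0.5) {
  if (!all(is.finite(position))) abort("`position` must be finite.")
  mask <- sigmoid(position) > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Redundancy penalty of a gene subset
#'
#' Mean absolute pairwise correlation among the selected genes, in
#' `[0, 1]`; 0 when exactly one gene is selected. A zero-variance gene's
#' pairwise correlations are treated as 0 (with a warning), not `NA`.
#'
#' @param data Data frame of numeric gene columns (a class column, if
#'   present, is ignored by name) or a numeric matrix.
#' @param mask Logical vector over the gene columns with at least one `TRUE`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param class_col Name of the class column to drop when `data` is a data
#'   frame.
#' @return A scalar in `[0, 1]`.
#' @examples
#' d <- generate_expression(synthetic_spec(50, 6, n_informative = 2,
#'                                         n_redundant = 2, seed = 1))
#' redundancy_penalty(d, rep(TRUE, 6))
#' @export
redundancy_penalty <- function(data, mask, method = c("pearson", "spearman"),
                               class_col = "class") {
  method <- match.arg(method)
  x <- if (is.matrix(data)) data else {
    as.matrix(data[setdiff(names(data), class_col)])
  }
  if (length(mask) != ncol(x)) abort("`mask` length must match the gene count.")
  if (!any(mask)) abort("`mask` selects no genes.")
  xs <- x[, mask, drop = FALSE]
  if (ncol(xs) == 1) return(0)
  zero_var <- col_sds(xs) == 0
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance gene(s) among selected; correlations set to 0.",
                 sum(zero_var)))
    if (sum(!zero_var) < 2) return(0)
  }
  cm <- suppressWarnings(stats::cor(xs, method = method))
  cm[!is.finite(cm)] <- 0
  n <- ncol(xs)
  mean(abs(cm[upper.tri(cm)]))
}

#' Combine the fitness components of a gene subset
#'
#' Evaluates `alpha * A + (1 - alpha) * (1 - Ns/Nt) - W * P` for given
#' accuracy, subset size and redundancy penalty. The value is at most 1 and
#' at least `-W`.
#'
#' @param accuracy Inner cross-validated accuracy `A` in `[0, 1]`.
#' @param n_selected Number of selected genes `Ns`.
#' @param n_total Total number of genes `Nt`.
#' @param penalty Redundancy penalty `P(s)` in `[0, 1]`.
#' @param config A [fitness_config()].
#' @return The scalar fitness.
#' @examples
#' combine_fitness(0.95, 100, 2000, 0.2) # 0.93
#' @export
combine_fitness <- function(accuracy, n_selected, n_total, penalty,
                            config = fitness_config()) {
  a <- config$alpha_weight
  a * accuracy + (1 - a) * (1 - n_selected / n_total) -
    config$redundancy_weight * penalty
}

# Inner CV accuracy of `spec` on the masked genes, using a fixed fold
# assignment so repeated evaluations of the same mask agree exactly.
masked_cv_accuracy <- function(x, y, mask, spec, folds) {
  xs <- x[, mask, drop = FALSE]
  correct <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred <- fit_predict_matrix(spec, xs[!te, , drop = FALSE], y[!te],
                               xs[te, , drop = FALSE])$labels
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Fitness of a gene mask on a dataset
#'
#' Scores a gene subset with the composite fitness: inner stratified
#' cross-validated accuracy of the wrapped classifier on the selected genes,
#' a sparsity reward, and the redundancy penalty (see [fitness_config()]).
#' Fold assignment is derived from `seed`, so the same `(data, mask,
#' classifier, config, seed)` always reproduces the same value.
#'
#' @param data Data frame of gene columns plus the class column.
#' @param mask Logical gene mask (at least one `TRUE`).
#' @param classifier A [classifier_spec()].
#' @param config A [fitness_config()].
#' @param class_col Name of the class column.
#' @param seed Integer seed fixing the inner folds.
#' @return The scalar fitness; the inner accuracy and penalty are attached
#'   as attributes `accuracy` and `penalty`.
#' @examples
#' d <- generate_expression(synthetic_spec(40, 10, n_informative = 3,
#'                                         n_redundant = 0, seed = 1))
#' mask_fitness(d, truth_genes(d) == names(d)[1:10], classifier_spec("knn"),
#'              seed = 1)
#' @export
mask_fitness <- function(data, mask, classifier = classifier_spec("knn"),
                         config = fitness_config(), class_col = "class",
                         seed = NULL) {
  ds <- split_dataset(data, class_col)
  folds <- make_folds(ds$y, config$inner_cv_folds, seed = seed)
  acc <- masked_cv_accuracy(ds$x, ds$y, mask, classifier, folds)
  pen <- redundancy_penalty(ds$x, mask, method = config$cor_method)
  out <- combine_fitness(acc, sum(mask), length(mask), pen, config)
  attr(out, "accuracy") <- acc
  attr(out, "penalty") <- pen
  out
}

#' Adaptive bit-flip mutation of a gene mask
#'
#' Flips each bit independently with the linearly decaying rate
#' `rate_max - (rate_max - rate_min) * t / n_iter`, mirroring the adaptive
#' exploration-factor schedule: broad mutation early, fine perturbation
#' late. An emptied mask is repaired by re-selecting one uniformly chosen
#' gene.
#'
#' @param mask Logical gene mask.
#' @param t Current iteration.
#' @param n_iter Total iterations.
#' @param config A [fitness_config()] carrying the rate endpoints.
#' @param rate Optional pinned flip probability overriding the schedule.
#' @return A logical mask with at least one `TRUE`.
#' @examples
#' set.seed(1)
#' mutate_mask(rep(TRUE, 10), t = 0, n_iter = 100)
#' @export
mutate_mask <- function(mask, t, n_iter, config = fitness_config(),
                        rate = NULL) {
  p <- rate %||% (config$mutation_rate_max -
    (config$mutation_rate_max - config$mutation_rate_min) * t / n_iter)
  flip <- stats::runif(length(mask)) < p
  out <- xor(mask, flip)
  if (!any(out)) out[sample.int(length(out), 1)] <- TRUE
  out
}

new_gene_selection <- function(mask, genes, fitness, accuracy, penalty,
                               history, n_evals, classifier, epo, fitness_cfg,
                               seed, method, gene_ids = NULL) {
  if (!is.null(gene_ids)) names(mask) <- gene_ids
  structure(
    list(mask = mask, genes = genes, fitness = fitness,
         accuracy_inner = accuracy, penalty = penalty,
         n_selected = sum(mask), n_genes = length(mask),
         history = history, n_evals = n_evals,
         classifier = classifier, epo = epo, fitness_config = fitness_cfg,
         seed = seed, method = method),
    class = "gene_selection"
  )
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> (%s)\n", x$method))
  cat(sprintf("  %d of %d genes selected; fitness %.4f (inner accuracy %.4f, redundancy %.4f)\n",
              x$n_selected, x$n_genes, x$fitness, x$accuracy_inner, x$penalty))
  cat(sprintf("  %d fitness evaluations, seed %s\n", x$n_evals,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' Select genes with Eagle Prey Optimization
#'
#' Runs the continuous EPO optimizer over positions in `[-4, 4]` per gene,
#' binarizing each position into a mask ([binarize()]) and scoring it with
#' the composite fitness. Whenever a candidate improves, its mask is
#' additionally perturbed by the adaptive bit-flip mutation
#' ([mutate_mask()]) and the mutant is adopted if it scores higher (the
#' mutation is applied in position space by flipping the sign of the
#' mutated coordinates). Inner cross-validation folds are fixed once per
#' run, so the whole search is deterministic under `seed`.
#'
#' @param data Data frame of gene columns plus the class column (the
#'   training partition; keep a separate partition for final evaluation).
#' @param classifier A [classifier_spec()] wrapped inside the fitness.
#' @param epo An [epo_config()].
#' @param fitness A [fitness_config()].
#' @param class_col Name of the class column.
#' @param seed Integer seed (defaults to `epo$seed`).
#' @return An object of class `gene_selection`: the best mask, the selected
#'   gene ids, its fitness and diagnostics, the per-iteration best-fitness
#'   history, and the evaluation count.
#' @examples
#' d <- generate_expression(synthetic_spec(40, 12, n_informative = 3,
#'                                         n_redundant = 0, seed = 1))
#' sel <- select_genes(d, epo = epo_config(n_pop = 8, n_iter = 10, seed = 1))
#' sel$genes
#' @export
select_genes <- function(data, classifier = classifier_spec("knn"),
                         epo = epo_config(), fitness = fitness_config(),
                         class_col = "class", seed = epo$seed) {
  ds <- split_dataset(data, class_col)
  p <- ncol(ds$x)
  folds <- make_folds(ds$y, fitness$inner_cv_folds, seed = child_seed(seed %||% 0L, 1))
  n_evals <- 0L
  # memoize by mask: converging populations re-evaluate identical subsets,
  # and the inner folds are fixed, so cached values are exact
  cache <- new.env(hash = TRUE, parent = emptyenv())
  eval_mask <- function(mask) {
    n_evals <<- n_evals + 1L
    padded <- c(mask, logical(8 * ceiling(length(mask) / 8) - length(mask)))
    key <- paste(packBits(padded, type = "raw"), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    acc <- masked_cv_accuracy(ds$x, ds$y, mask, classifier, folds)
    pen <- redundancy_penalty(ds$x, mask, method = fitness$cor_method)
    f <- combine_fitness(acc, sum(mask), p, pen, fitness)
    cache[[key]] <- f
    f
  }
  objective <- function(position) {
    eval_mask(binarize(position, fitness$transfer_threshold))
  }
  hook <- function(position, fit, t) {
    mask <- binarize(position, fitness$transfer_threshold)
    mutant <- mutate_mask(mask, t, max(1L, epo$n_iter), fitness)
    changed <- xor(mask, mutant)
    if (!any(changed)) return(NULL)
    f2 <- eval_mask(mutant)
    if (f2 <= fit) return(NULL)
    # realize the mutant in position space: sign-flip the changed
    # coordinates (sigmoid(-x) = 1 - sigmoid(x) crosses the 0.5 threshold);
    # a zero coordinate flipped on gets a positive nudge.
    pos2 <- position
    pos2[changed] <- ifelse(pos2[changed] == 0, 1, -pos2[changed])
    list(position = pos2, fitness = f2)
  }

  res <- run_epo(
    objective,
    n_dim = p, lower = -4, upper = 4, config = epo, seed = seed,
    accept_hook = hook
  )
  best_mask <- binarize(res$best_position, fitness$transfer_threshold)
  acc <- masked_cv_accuracy(ds$x, ds$y, best_mask, classifier, folds)
  pen <- redundancy_penalty(ds$x, best_mask, method = fitness$cor_method)
  best_fit <- combine_fitness(acc, sum(best_mask), p, pen, fitness)
  new_gene_selection(
    mask = best_mask, genes = colnames(ds$x)[best_mask], fitness = best_fit,
    accuracy = acc, penalty = pen, history = res$history,
    n_evals = n_evals, classifier = classifier, epo = epo,
    fitness_cfg = fitness, seed = seed, method = "epo", gene_ids = colnames(ds$x)
  )
}

#' Exhaustive gene-subset oracle
#'
#' Evaluates the composite fitness of every non-empty gene subset and
#' returns the global maximizer (ties broken towards the lexicographically
#' smallest mask, i.e. the subset whose earliest differing gene is
#' unselected). Intended as a ground-truth oracle for small instances;
#' refuses more than 20 genes (over a million subsets).
#'
#' @inheritParams select_genes
#' @param fitness A [fitness_config()].
#' @param seed Seed fixing the inner folds; use the same seed as the
#'   EPO run being compared.
#' @return A `gene_selection` object with `method = "exhaustive"`.
#' @examples
#' d <- generate_expression(synthetic_spec(30, 6, n_informative = 2,
#'                                         n_redundant = 0, seed = 1))
#' exhaustive_search(d, seed = 1)$n_evals # 63 subsets
#' @export
exhaustive_search <- function(data, classifier = classifier_spec("knn"),
                              fitness = fitness_config(),
                              class_col = "class", seed = NULL) {
  ds <- split_dataset(data, class_col)
  p <- ncol(ds$x)
  if (p > 20) abort("Exhaustive search refused for more than 20 genes.")
  folds <- make_folds(ds$y, fitness$inner_cv_folds, seed = child_seed(seed %||% 0L, 1))
  best_fit <- -Inf
  best_mask <- NULL
  n_evals <- 0L
  for (code in seq_len(2^p - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1)))
    acc <- masked_cv_accuracy(ds$x, ds$y, mask, classifier, folds)
    pen <- redundancy_penalty(ds$x, mask, method = fitness$cor_method)
    f <- combine_fitness(acc, sum(mask), p, pen, fitness)
    n_evals <- n_evals + 1L
    if (f > best_fit) {
      best_fit <- f
      best_mask <- mask
    }
    # ties keep the earlier (lexicographically smaller) mask: the code order
    # enumerates masks with gene 1 varying fastest, so strictly-greater
    # replacement alone does not guarantee lexicographic order; resolve
    # explicitly on exact ties.
    else if (f == best_fit && mask_lex_lt(mask, best_mask)) {
      best_mask <- mask
    }
  }
  acc <- masked_cv_accuracy(ds$x, ds$y, best_mask, classifier, folds)
  pen <- redundancy_penalty(ds$x, best_mask, method = fitness$cor_method)
  new_gene_selection(
    mask = best_mask, genes = colnames(ds$x)[best_mask], fitness = best_fit,
    accuracy = acc, penalty = pen,
    history = tibble(iteration = 0L, best_fitness = best_fit,
                     explore_factor = NA_real_, phase = "exhaustive"),
    n_evals = n_evals, classifier = classifier, epo = NULL,
    fitness_cfg = fitness, seed = seed, method = "exhaustive", gene_ids = colnames(ds$x)
  )
}

# TRUE if mask a precedes mask b lexicographically (FALSE < TRUE per gene).
mask_lex_lt <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && !a[d[1]]
}

#' Budget-fair uniform random-subset baseline
#'
#' Samples `n_evals` gene masks uniformly (each gene included independently
#' with probability 1/2, empty masks repaired) and returns the best under
#' the same composite fitness and inner folds as [select_genes()]. With
#' `n_evals` set to an EPO run's evaluation count this is the budget-fair
#' random-search comparator.
#'
#' @inheritParams select_genes
#' @param n_evals Number of fitness evaluations to spend.
#' @return A `gene_selection` object with `method = "random_search"`.
#' @export
random_search <- function(data, n_evals, classifier = classifier_spec("knn"),
                          fitness = fitness_config(), class_col = "class",
                          seed = NULL) {
  check_number(n_evals, "n_evals", lower = 1, integer = TRUE)
  ds <- split_dataset(data, class_col)
  p <- ncol(ds$x)
  folds <- make_folds(ds$y, fitness$inner_cv_folds, seed = child_seed(seed %||% 0L, 1))
  best_fit <- -Inf
  best_mask <- NULL
  hist <- numeric(n_evals)
  with_seed(seed, {
    for (i in seq_len(n_evals)) {
      mask <- stats::runif(p) < 0.5
      if (!any(mask)) mask[sample.int(p, 1)] <- TRUE
      acc <- masked_cv_accuracy(ds$x, ds$y, mask, classifier, folds)
      pen <- redundancy_penalty(ds$x, mask, method = fitness$cor_method)
      f <- combine_fitness(acc, sum(mask), p, pen, fitness)
      if (f > best_fit) {
        best_fit <- f
        best_mask <- mask
      }
      hist[i] <- best_fit
    }
  })
  acc <- masked_cv_accuracy(ds$x, ds$y, best_mask, classifier, folds)
  pen <- redundancy_penalty(ds$x, best_mask, method = fitness$cor_method)
  new_gene_selection(
    mask = best_mask, genes = colnames(ds$x)[best_mask], fitness = best_fit,
    accuracy = acc, penalty = pen,
    history = tibble(iteration = seq_len(n_evals), best_fitness = hist,
                     explore_factor = NA_real_, phase = "random"),
    n_evals = n_evals, classifier = classifier, epo = NULL,
    fitness_cfg = fitness, seed = seed, method = "random_search", gene_ids = colnames(ds$x)
  )
}
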