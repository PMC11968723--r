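#' Confusion-matrix classification metrics from binary counts
#'
#' Computes accuracy, precision, recall, F1 (harmonic mean of precision and
#' recall), and specificity from the four cells of a binary confusion
#' matrix. An undefined ratio (zero denominator) is reported as 0 and the
#' metric's name recorded in the `flags` attribute rather than dropped.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`, `specificity`; undefined metrics are flagged in
#'   `attr(, "flags")`.
#' @examples
#' metric_set_counts(tp = 40, tn = 30, fp = 10, fn = 20)
#' @export
metric_set_counts <- function(tp, tn, fp, fn) {
  for (v in list(tp, tn, fp, fn)) check_number(v, "count", lower = 0, integer = TRUE)
  n <- tp + tn + fp + fn
  if (n < 1) abort("At least one instance is required.")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  out <- tibble(
    accuracy = (tp + tn) / n,
    precision = precision,
    recall = recall,
    f1 = f1,
    specificity = safe(tn, tn + fp, "specificity")
  )
  attr(out, "flags") <- flags
  out
}

# Rank-statistic AUC (Mann-Whitney with midranks for ties): probability a
# random positive outscores a random negative.
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics from predictions
#'
#' Computes the six evaluation metrics — accuracy, precision, recall, F1,
#' specificity and AUC-ROC — from true and predicted labels. For two
#' classes, the second factor level of `truth` is the positive class (or
#' set `positive`). With more than two classes each label-based metric is
#' the macro average over one-vs-rest reductions, and AUC is the macro
#' one-vs-rest rank-statistic AUC over the per-class score columns.
#'
#' @param truth Factor (or coercible) of true labels.
#' @param estimate Factor of predicted labels on the same levels.
#' @param scores Optional numeric class scores: for two classes a vector of
#'   positive-class scores (or a matrix with a positive-class column); for
#'   multiclass a matrix with one column per class level.
#' @param positive Positive class label for the binary case.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity`, `auc_roc` (`NA` without scores); undefined ratios are
#'   reported as 0 and flagged in `attr(, "flags")`.
#' @examples
#' truth <- factor(c("a", "a", "b", "b"))
#' est <- factor(c("a", "b", "b", "b"), levels = c("a", "b"))
#' metric_set(truth, est, scores = c(0.2, 0.6, 0.8, 0.9))
#' @export
metric_set <- function(truth, estimate, scores = NULL, positive = NULL) {
  truth <- as.factor(truth)
  estimate <- factor(estimate, levels = levels(truth))
  if (length(truth) != length(estimate)) abort("Length mismatch.")
  if (length(truth) < 1) abort("At least one instance is required.")
  lev <- levels(truth)
  flags <- character(0)

  if (length(lev) == 2) {
    pos <- positive %||% lev[2]
    if (!pos %in% lev) abort("`positive` is not a level of `truth`.")
    tp <- sum(truth == pos & estimate == pos)
    tn <- sum(truth != pos & estimate != pos)
    fp <- sum(truth != pos & estimate == pos)
    fn <- sum(truth == pos & estimate != pos)
    out <- metric_set_counts(tp, tn, fp, fn)
    flags <- attr(out, "flags")
    auc <- NA_real_
    if (!is.null(scores)) {
      s <- if (is.matrix(scores) || is.data.frame(scores)) {
        as.matrix(scores)[, pos]
      } else scores
      auc <- auc_rank(s, truth == pos)
    }
    out$auc_roc <- auc
  } else {
    per_class <- lapply(lev, function(lv) {
      tp <- sum(truth == lv & estimate == lv)
      tn <- sum(truth != lv & estimate != lv)
      fp <- sum(truth != lv & estimate == lv)
      fn <- sum(truth == lv & estimate != lv)
      m <- metric_set_counts(tp, tn, fp, fn)
      flags <<- union(flags, attr(m, "flags"))
      m
    })
    macro <- dplyr::summarise(dplyr::bind_rows(per_class),
                              dplyr::across(dplyr::everything(), mean))
    auc <- NA_real_
    if (!is.null(scores)) {
      sc <- as.matrix(scores)
      if (is.null(colnames(sc)) && ncol(sc) == length(lev)) colnames(sc) <- lev
      auc <- mean(vapply(lev, function(lv) {
        auc_rank(sc[, lv], truth == lv)
      }, numeric(1)))
    }
    out <- macro
    out$accuracy <- mean(truth == estimate) # overall, not macro
    out$auc_roc <- auc
  }
  attr(out, "flags") <- flags
  out
}

#' Stratified k-fold cross-validation error
#'
#' Mean held-out 0-1 loss of a classifier over `k` stratified folds,
#' optionally restricted to a gene mask. If the smallest class has fewer
#' than `k` members the fold count is reduced with a warning; `k = n`
#' performs leave-one-out on balanced data.
#'
#' @param data Data frame of gene columns plus the class column.
#' @param classifier A [classifier_spec()].
#' @param k Number of folds (default 5).
#' @param mask Optional logical gene mask.
#' @param class_col Name of the class column.
#' @param seed Seed fixing the fold assignment.
#' @return The scalar misclassification error in `[0, 1]`.
#' @examples
#' d <- generate_expression(synthetic_spec(40, 10, n_informative = 3,
#'                                         n_redundant = 0, seed = 1))
#' kfold_error(d, classifier_spec("knn"), seed = 1)
#' @export
kfold_error <- function(data, classifier = classifier_spec("knn"), k = 5,
                        mask = NULL, class_col = "class", seed = NULL) {
  ds <- split_dataset(data, class_col)
  mask <- mask %||% rep(TRUE, ncol(ds$x))
  folds <- make_folds(ds$y, k, seed = seed)
  1 - masked_cv_accuracy(ds$x, ds$y, mask, classifier, folds)
}

#' Relative-overfitting blend weight of the 0.632+ estimator
#'
#' `w = 0.632 / (1 - 0.368 R)` with the relative overfitting rate `R`
#' clipped to `[0, 1]`; `w` runs from 0.632 (no overfitting) to 1
#' (overfitting at the no-information level), monotonically.
#'
#' @param R Relative overfitting rate (any real; clipped to `[0, 1]`).
#' @return The blend weight in `[0.632, 1]`.
#' @examples
#' blend_weight(0) # 0.632
#' blend_weight(1) # 1
#' @export
blend_weight <- function(R) {
  R <- clamp(R, 0, 1)
  0.632 / (1 - 0.368 * R)
}

#' Mean distinct-instance fraction of bootstrap resamples
#'
#' Draws `B` bootstrap resamples of size `n` with replacement and returns
#' the mean fraction of distinct original instances per resample. As `n`
#' grows this converges to `1 - e^-1 ~ 0.632`, the constant anchoring the
#' 0.632+ estimator. Uses the current RNG state.
#'
#' @param n Resample (and population) size.
#' @param B Number of resamples.
#' @return Mean distinct fraction across the `B` resamples.
#' @examples
#' set.seed(1)
#' bootstrap_unique_fraction(200, 100)
#' @export
bootstrap_unique_fraction <- function(n, B) {
  check_number(n, "n", lower = 1, integer = TRUE)
  check_number(B, "B", lower = 1, integer = TRUE)
  mean(vapply(seq_len(B), function(b) {
    length(unique(sample.int(n, n, replace = TRUE))) / n
  }, numeric(1)))
}

#' 0.632+ bootstrap estimate of classification error
#'
#' Estimates prediction error by blending the optimistic resubstitution
#' error with the pessimistic leave-one-out bootstrap error. `B` bootstrap
#' resamples are drawn with replacement; the leave-one-out bootstrap error
#' averages, for each instance, the 0-1 losses of the models whose resample
#' excluded it. The no-information rate `Gamma` evaluates the full-data
#' model over all target/predictor pairings, the relative overfitting rate
#' `R = (err_boot - err_resub) / (Gamma - err_resub)` is clipped to
#' `[0, 1]` (and defined as 0 when `Gamma` equals the resubstitution
#' error), and the blend weight is `w = 0.632 / (1 - 0.368 R)`, giving
#' `err_632plus = (1 - w) err_resub + w err_boot`.
#'
#' @param data Data frame of gene columns plus the class column.
#' @param classifier A [classifier_spec()].
#' @param B Number of bootstrap resamples (default 50).
#' @param mask Optional logical gene mask restricting the features.
#' @param class_col Name of the class column.
#' @param seed Seed fixing the resamples.
#' @return An object of class `error_632`: `err_resub`, `err_loo_boot`,
#'   `err_632plus`, `w_blend`, `R_overfit`, `gamma_noinfo`, `B`, and
#'   `n_excluded` (instances present in every resample, excluded from the
#'   leave-one-out average).
#' @examples
#' d <- generate_expression(synthetic_spec(40, 10, n_informative = 3,
#'                                         n_redundant = 0, seed = 1))
#' bootstrap_632plus(d, classifier_spec("knn"), B = 10, seed = 1)
#' @export
bootstrap_632plus <- function(data, classifier = classifier_spec("knn"),
                              B = 50, mask = NULL, class_col = "class",
                              seed = NULL) {
  check_number(B, "B", lower = 1, integer = TRUE)
  ds <- split_dataset(data, class_col)
  n <- nrow(ds$x)
  if (n < 10) abort("At least 10 instances are required.")
  mask <- mask %||% rep(TRUE, ncol(ds$x))
  x <- ds$x[, mask, drop = FALSE]
  y <- ds$y

  # resubstitution fit on the full data
  full_pred <- fit_predict_matrix(classifier, x, y, x)$labels
  err_resub <- mean(full_pred != y)
  # no-information rate: all (target i, prediction j) pairings
  gamma <- mean(outer(as.integer(y), as.integer(full_pred), "!="))

  loss_sum <- numeric(n)
  loss_cnt <- integer(n)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) == 0) next
      yb <- droplevels(y[idx])
      if (nlevels(yb) < 2) next # degenerate resample: no usable model
      pred <- fit_predict_matrix(classifier, x[idx, , drop = FALSE], y[idx],
                                 x[oob, , drop = FALSE])$labels
      miss <- as.numeric(pred != y[oob])
      loss_sum[oob] <- loss_sum[oob] + miss
      loss_cnt[oob] <- loss_cnt[oob] + 1L
    }
  })
  covered <- loss_cnt > 0
  n_excluded <- sum(!covered)
  if (n_excluded > 0) {
    warn(sprintf("%d instance(s) appeared in every bootstrap resample; excluded from the leave-one-out average.",
                 n_excluded))
  }
  if (!any(covered)) abort("No out-of-bootstrap instances; increase B.")
  err_boot <- mean(loss_sum[covered] / loss_cnt[covered])

  R <- if (gamma == err_resub) 0 else {
    clamp((err_boot - err_resub) / (gamma - err_resub), 0, 1)
  }
  w <- blend_weight(R)
  structure(
    list(err_resub = err_resub, err_loo_boot = err_boot,
         err_632plus = (1 - w) * err_resub + w * err_boot,
         w_blend = w, R_overfit = R, gamma_noinfo = gamma,
         B = as.integer(B), n_excluded = n_excluded, seed = seed),
    class = "error_632"
  )
}

#' @export
print.error_632 <- function(x, ...) {
  cat("<error_632>\n")
  cat(sprintf("  resubstitution %.4f | leave-one-out bootstrap %.4f | 0.632+ %.4f\n",
              x$err_resub, x$err_loo_boot, x$err_632plus))
  cat(sprintf("  blend weight %.4f, overfitting rate %.4f, no-information rate %.4f (B = %d)\n",
              x$w_blend, x$R_overfit, x$gamma_noinfo, x$B))
  invisible(x)
}

#' Paired significance tests between two runs of scores
#'
#' Compares paired performance values (e.g. per-seed accuracies of two
#' selectors) with a paired t-test, a Wilcoxon signed-rank test (exact for
#' up to 25 non-zero differences, normal approximation above), Cohen's d on
#' the paired differences (mean difference / SD of differences), and the
#' 95% t confidence interval of the mean difference. Degenerate cases are
#' flagged: all-zero differences give a Wilcoxon p of 1 and an undefined
#' (`NA`) d; nonzero constant differences give an undefined d.
#'
#' @param values_a,values_b Equal-length paired numeric vectors, length >= 5.
#' @return A one-row tibble: `n`, `mean_a`, `mean_b`, `mean_diff`, `t_p`,
#'   `wilcoxon_p`, `cohens_d`, `ci_low`, `ci_high`; degenerate branches
#'   noted in `attr(, "flags")`.
#' @examples
#' paired_tests(c(0.91, 0.92, 0.90, 0.93, 0.91, 0.92),
#'              c(0.89, 0.90, 0.88, 0.91, 0.90, 0.89))
#' @export
paired_tests <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) abort("Paired vectors must have equal length.")
  n <- length(values_a)
  if (n < 5) abort("At least 5 pairs are required.")
  d <- values_a - values_b
  flags <- character(0)
  sd_d <- stats::sd(d)
  # treat numerically constant differences (e.g. an exact constant shift
  # computed in floating point) as zero-variance
  if (sd_d < 1e-10 * max(1, abs(mean(d)))) sd_d <- 0

  if (all(d == 0)) {
    flags <- c(flags, "all differences zero")
    t_p <- 1
    w_p <- 1
    cd <- 0
    ci <- c(0, 0)
  } else if (sd_d == 0) {
    flags <- c(flags, "zero-variance differences")
    t_p <- 0
    w_p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = TRUE,
                         exact = n <= 25)$p.value
    )
    cd <- NA_real_
    ci <- c(mean(d), mean(d))
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    t_p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
    w_p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = TRUE,
                         exact = sum(d != 0) <= 25)$p.value
    )
    cd <- mean(d) / sd_d
  }
  out <- tibble(
    n = n, mean_a = mean(values_a), mean_b = mean(values_b),
    mean_diff = mean(d), t_p = t_p, wilcoxon_p = w_p, cohens_d = cd,
    ci_low = ci[1], ci_high = ci[2]
  )
  attr(out, "flags") <- flags
  out
}
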