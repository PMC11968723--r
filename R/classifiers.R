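#' Specify one of the five wrapped classifiers
#'
#' A uniform adapter over the learners used to score gene subsets:
#' a CART decision tree, a random forest, k-nearest neighbours, an RBF
#' support vector machine, and a single-hidden-layer backpropagation neural
#' network. The wrapper loop and the error estimators treat all five
#' interchangeably through [fit_predict()].
#'
#' Hyperparameters (all overridable through `...`):
#' * `decision_tree`: `minsplit` (20), `cp` (0.01), `maxdepth` (30)
#' * `random_forest`: `num_trees` (100), `mtry` (learner default)
#' * `knn`: `k` (5)
#' * `svm`: `cost` (1), `gamma` (1/p), `kernel` ("radial")
#' * `mlp`: `hidden` (32), `decay` (0.01), `maxit` (200)
#'
#' Features are standardized with train-fitted mean and variance for the
#' distance- and margin-based learners (`knn`, `svm`, `mlp`); tree learners
#' consume raw values.
#'
#' @param learner One of `"knn"`, `"decision_tree"`, `"random_forest"`,
#'   `"svm"`, `"mlp"`; stored as the spec's `kind`. (The argument is not
#'   named `kind` so that the `k` hyperparameter of `knn` cannot partially
#'   match it.)
#' @param ... Hyperparameter overrides; unknown names are rejected.
#' @param seed Integer seed fixing the stochastic learners' fits.
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("knn", k = 3)
#' classifier_spec("random_forest", num_trees = 200, seed = 1)
#' @export
classifier_spec <- function(learner = c("knn", "decision_tree",
                                        "random_forest", "svm", "mlp"),
                            ..., seed = NULL) {
  kind <- match.arg(learner)
  defaults <- switch(kind,
    decision_tree = list(minsplit = 20, cp = 0.01, maxdepth = 30),
    random_forest = list(num_trees = 100, mtry = NULL),
    knn = list(k = 5),
    svm = list(cost = 1, gamma = NULL, kernel = "radial"),
    mlp = list(hidden = 32, decay = 0.01, maxit = 200)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown hyperparameters for %s: %s.",
                  kind, paste(unknown, collapse = ", ")))
  }
  hyper <- utils::modifyList(defaults, override)
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)
  structure(
    list(kind = kind, hyper = hyper,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- x$hyper[!vapply(x$hyper, is.null, TRUE)]
  cat(sprintf("<classifier_spec> %s (%s)\n", x$kind,
              paste(names(hp), unlist(hp), sep = "=", collapse = ", ")))
  invisible(x)
}

needs_scaling <- function(spec) spec$kind %in% c("knn", "svm", "mlp")

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- col_sds(x)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")

# kNN class-score matrix: fraction of the k nearest train neighbours in each
# class (needed for AUC; class::knn only reports the winning-class fraction).
knn_scores <- function(xtr, ytr, xte, k) {
  lev <- levels(ytr)
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * tcrossprod(xte, xtr)
  scores <- matrix(0, nrow(xte), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(xte))) {
    nn <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
    tab <- table(factor(ytr[nn], levels = lev))
    scores[i, ] <- as.numeric(tab) / length(nn)
  }
  scores
}

# Core fit + predict on plain matrices; returns factor labels and, when
# requested, a class-score matrix (columns = class levels).
fit_predict_matrix <- function(spec, xtr, ytr, xte, scores = FALSE) {
  ytr <- droplevels(as.factor(ytr))
  if (nlevels(ytr) < 2) abort("Training data has a single class.")
  if (ncol(xtr) != ncol(xte)) abort("Feature-count mismatch between train and test.")
  lev <- levels(ytr)
  if (needs_scaling(spec)) {
    sc <- scale_fit(xtr)
    xtr <- scale_apply(xtr, sc)
    xte <- scale_apply(xte, sc)
  }
  hp <- spec$hyper
  out <- with_seed(spec$seed %||% 0L, switch(spec$kind,
    knn = {
      k <- min(hp$k, nrow(xtr))
      pred <- class::knn(xtr, xte, ytr, k = k)
      list(labels = pred,
           scores = if (scores) knn_scores(xtr, ytr, xte, k) else NULL)
    },
    decision_tree = {
      df <- as.data.frame(xtr); names(df) <- paste0("f", seq_len(ncol(xtr)))
      df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = hp$minsplit, cp = hp$cp,
                            maxdepth = hp$maxdepth))
      te <- as.data.frame(xte); names(te) <- paste0("f", seq_len(ncol(xte)))
      prob <- stats::predict(fit, te, type = "prob")
      list(labels = factor(lev[max.col(prob, "first")], levels = lev),
           scores = if (scores) prob else NULL)
    },
    random_forest = {
      fit <- randomForest::randomForest(
        xtr, ytr, ntree = hp$num_trees,
        mtry = hp$mtry %||% max(1, floor(sqrt(ncol(xtr)))))
      prob <- stats::predict(fit, xte, type = "prob")
      list(labels = factor(lev[max.col(prob, "first")], levels = lev),
           scores = if (scores) prob else NULL)
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = hp$kernel, cost = hp$cost,
                        gamma = hp$gamma %||% (1 / ncol(xtr)),
                        probability = scores)
      pred <- stats::predict(fit, xte, probability = scores)
      sc_mat <- NULL
      if (scores) {
        sc_mat <- attr(pred, "probabilities")[, lev, drop = FALSE]
      }
      list(labels = factor(as.character(pred), levels = lev), scores = sc_mat)
    },
    mlp = {
      fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = hp$hidden,
                        decay = hp$decay, maxit = hp$maxit, softmax = TRUE,
                        trace = FALSE, MaxNWts = 100000)
      prob <- stats::predict(fit, xte)
      colnames(prob) <- lev
      list(labels = factor(lev[max.col(prob, "first")], levels = lev),
           scores = if (scores) prob else NULL)
    }
  ))
  out
}

#' Fit a classifier on training data and predict test labels
#'
#' Fits the learner described by a [classifier_spec()] on the training
#' partition and returns one predicted label per test instance, plus
#' per-class membership scores when `scores = TRUE`. Stochastic learners
#' (random forest, neural network) are seeded from the spec, so identical
#' inputs give identical predictions.
#'
#' @param spec A [classifier_spec()].
#' @param train Data frame of training instances: numeric gene columns plus
#'   the class column.
#' @param test_features Data frame or matrix of test instances with the same
#'   gene columns (no class column required).
#' @param class_col Name of the class column in `train`.
#' @param scores Return per-class score columns (`.score_<class>`)?
#' @return A tibble with a `.pred` factor column (one row per test
#'   instance), plus score columns when requested.
#' @examples
#' d <- generate_expression(synthetic_spec(40, 10, n_informative = 3,
#'                                         n_redundant = 0, seed = 1))
#' fit_predict(classifier_spec("knn"), d, d[-11])
#' @export
fit_predict <- function(spec, train, test_features, class_col = "class",
                        scores = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"))
  tr <- split_dataset(train, class_col)
  te <- test_features
  if (is.data.frame(te)) {
    te <- te[setdiff(names(te), class_col)]
    miss <- setdiff(colnames(tr$x), names(te))
    if (length(miss) > 0) {
      abort(sprintf("Test features missing columns: %s.",
                    paste(utils::head(miss, 5), collapse = ", ")))
    }
    te <- as.matrix(te[, colnames(tr$x), drop = FALSE])
  }
  res <- fit_predict_matrix(spec, tr$x, tr$y, te, scores = scores)
  out <- tibble(.pred = res$labels)
  if (scores && !is.null(res$scores)) {
    sc <- as_tibble(as.data.frame(res$scores))
    names(sc) <- paste0(".score_", names(sc))
    out <- dplyr::bind_cols(out, sc)
  }
  out
}
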