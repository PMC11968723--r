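#' Specify a synthetic microarray-like dataset
#'
#' Describes a gene-expression dataset with planted structure on the
#' standard-normal log-intensity scale: `n_informative` genes whose
#' class-conditional means are spaced `effect_size` standard deviations
#' apart, `n_redundant` genes that are noisy correlated copies of randomly
#' chosen informative genes (population correlation `redundancy_rho`), and
#' pure Normal(0, 1) noise genes for the remainder. The planted
#' (informative + redundant) genes form the known truth mask used to score
#' recovery by feature selection.
#'
#' @param n_instances Number of samples (rows).
#' @param n_genes Total number of genes (feature columns).
#' @param n_classes Number of class labels, 2 to 4.
#' @param n_informative Number of genes carrying class signal.
#' @param n_redundant Number of correlated copies of informative genes.
#' @param effect_size Spacing of adjacent class means in units of `noise_sd`
#'   (default 2.0, a strong microarray-scale group separation).
#' @param redundancy_rho Population correlation between a redundant gene and
#'   its parent, in `[0, 1)` (default 0.9).
#' @param noise_sd Within-class standard deviation of informative genes
#'   (default 1).
#' @param class_proportions Class mix summing to 1; equal by default.
#' @param intensity_scale `"log"` (standard-normal log-intensity, default)
#'   or `"raw"` (exponentiated to a log-normal raw-intensity scale).
#' @param seed Integer seed; fixes the dataset exactly.
#' @return An object of class `synthetic_spec`.
#' @examples
#' synthetic_spec(60, 2000, seed = 1)
#' @export
synthetic_spec <- function(n_instances, n_genes, n_classes = 2,
                           n_informative = 10, n_redundant = 20,
                           effect_size = 2, redundancy_rho = 0.9,
                           noise_sd = 1, class_proportions = NULL,
                           intensity_scale = c("log", "raw"), seed = NULL) {
  check_number(n_instances, "n_instances", lower = 2, integer = TRUE)
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(n_classes, "n_classes", lower = 2, upper = 4, integer = TRUE)
  check_number(n_informative, "n_informative", lower = 1, integer = TRUE)
  check_number(n_redundant, "n_redundant", lower = 0, integer = TRUE)
  check_number(effect_size, "effect_size", lower = 0)
  check_number(redundancy_rho, "redundancy_rho", 0, 1)
  if (redundancy_rho >= 1) abort("`redundancy_rho` must be < 1.")
  check_number(noise_sd, "noise_sd", lower = 0, open = TRUE)
  if (n_informative + n_redundant > n_genes) {
    abort("More planted genes than genes: n_informative + n_redundant > n_genes.")
  }
  props <- class_proportions %||% rep(1 / n_classes, n_classes)
  if (length(props) != n_classes || any(props <= 0) ||
      abs(sum(props) - 1) > 1e-8) {
    abort("`class_proportions` must be positive and sum to 1.")
  }
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_instances = as.integer(n_instances), n_genes = as.integer(n_genes),
         n_classes = as.integer(n_classes),
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         effect_size = effect_size, redundancy_rho = redundancy_rho,
         noise_sd = noise_sd, class_proportions = props,
         intensity_scale = match.arg(intensity_scale),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d instances x %d genes, %d classes\n  planted: %d informative (effect %.2g sd) + %d redundant (rho %.2g)\n",
    x$n_instances, x$n_genes, x$n_classes, x$n_informative, x$effect_size,
    x$n_redundant, x$redundancy_rho))
  invisible(x)
}

#' Generate a synthetic gene-expression dataset
#'
#' Draws a dataset according to a [synthetic_spec()]. Class labels are
#' allocated deterministically to match `class_proportions` (largest
#' remainder) and shuffled. Informative gene `g` in class `c` is
#' `Normal(mu_c, noise_sd^2)` with class means centred and spaced
#' `effect_size * noise_sd` apart. A redundant gene standardizes its parent
#' by the parent's theoretical marginal moments and adds independent noise,
#' so its population correlation with the parent equals `redundancy_rho`.
#' Gene columns are named `g0001`, `g0002`, ...; planted genes are recorded
#' in the `truth_genes` attribute (see [truth_genes()]).
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble of `n_instances` rows: numeric gene columns and a
#'   `class` factor column, with attributes `truth_genes`,
#'   `informative_genes`, `redundant_genes` and `spec`.
#' @examples
#' d <- generate_expression(synthetic_spec(30, 50, seed = 1))
#' dim(d)
#' truth_genes(d)
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_instances
  p <- spec$n_genes
  k <- spec$n_classes

  with_seed(spec$seed, {
    counts <- floor(spec$class_proportions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- spec$class_proportions * n - counts
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    y <- sample(rep(seq_len(k), counts))

    mu <- (seq_len(k) - (k + 1) / 2) * spec$effect_size * spec$noise_sd
    x <- matrix(stats::rnorm(n * p), n, p)

    info_idx <- seq_len(spec$n_informative)
    for (g in info_idx) {
      x[, g] <- mu[y] + spec$noise_sd * x[, g]
    }

    red_idx <- if (spec$n_redundant > 0) {
      spec$n_informative + seq_len(spec$n_redundant)
    } else integer(0)
    if (length(red_idx) > 0) {
      # theoretical marginal moments of an informative gene
      m_marg <- sum(spec$class_proportions * mu)
      v_marg <- spec$noise_sd^2 +
        sum(spec$class_proportions * mu^2) - m_marg^2
      parents <- sample(info_idx, length(red_idx), replace = TRUE)
      rho <- spec$redundancy_rho
      for (j in seq_along(red_idx)) {
        z <- (x[, parents[j]] - m_marg) / sqrt(v_marg)
        x[, red_idx[j]] <- rho * z + sqrt(1 - rho^2) * x[, red_idx[j]]
      }
    }
    if (spec$intensity_scale == "raw") x <- exp(x)

    ids <- sprintf("g%0*d", max(4, nchar(p)), seq_len(p))
    colnames(x) <- ids
    out <- as_tibble(as.data.frame(x))
    out$class <- factor(paste0("c", y), levels = paste0("c", seq_len(k)))
    attr(out, "informative_genes") <- ids[info_idx]
    attr(out, "redundant_genes") <- ids[red_idx]
    attr(out, "truth_genes") <- ids[c(info_idx, red_idx)]
    attr(out, "spec") <- spec
    out
  })
}

#' Planted genes of a synthetic dataset
#'
#' @param data A tibble from [generate_expression()] (or any data frame
#'   carrying a `truth_genes` attribute).
#' @return Character vector of planted (informative + redundant) gene ids,
#'   or `NULL` when unknown.
#' @export
truth_genes <- function(data) attr(data, "truth_genes")

#' Benchmark dataset shape presets
#'
#' Specs matching the (genes, instances, classes) shapes of eight widely
#' used public microarray cancer datasets, with the package's default
#' planted-signal parameters. Only the shapes mirror the public benchmarks;
#' the expression values are synthetic.
#'
#' @param seed Base seed; preset `i` uses a seed derived from it.
#' @return Named list of [synthetic_spec()] objects: `colon`, `cns`,
#'   `breast`, `lung`, `ovarian`, `lymphoma`, `mll`, `srbct`.
#' @examples
#' table1_presets(seed = 1)[["colon"]]
#' @export
table1_presets <- function(seed = NULL) {
  shapes <- list(
    colon    = c(2000, 60, 2),
    cns      = c(7129, 60, 2),
    breast   = c(24481, 97, 2),
    lung     = c(12533, 181, 2),
    ovarian  = c(15154, 253, 2),
    lymphoma = c(4026, 62, 3),
    mll      = c(12582, 72, 3),
    srbct    = c(2308, 83, 4)
  )
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    out[[i]] <- synthetic_spec(
      n_instances = s[2], n_genes = s[1], n_classes = s[3],
      seed = if (is.null(seed)) NULL else child_seed(seed, i)
    )
  }
  out
}
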