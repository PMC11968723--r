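#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_point
#'   labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an EPO optimization run
#'
#' @param x An `epo_result` from [run_epo()].
#' @param ... Unused.
#' @return The per-iteration history tibble (`iteration`, `best_fitness`,
#'   `explore_factor`, `phase`).
#' @method tidy epo_result
#' @export
tidy.epo_result <- function(x, ...) x$history

#' @rdname tidy.epo_result
#' @return For `glance()`: a one-row run summary.
#' @method glance epo_result
#' @export
glance.epo_result <- function(x, ...) {
  tibble(
    best_fitness = x$best_fitness,
    n_dim = length(x$best_position),
    n_pop = x$config$n_pop,
    n_iter = x$config$n_iter,
    n_evals = x$n_evals,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a gene-selection result
#'
#' @param x A `gene_selection` from [select_genes()], [exhaustive_search()]
#'   or [random_search()].
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene`, `selected`.
#' @method tidy gene_selection
#' @export
tidy.gene_selection <- function(x, ...) {
  all_genes <- if (!is.null(names(x$mask))) names(x$mask) else {
    # genes holds the selected ids; reconstruct the full id order when known
    NULL
  }
  tibble(
    gene = all_genes %||% paste0("gene_", seq_along(x$mask)),
    selected = x$mask
  )
}

#' @rdname tidy.gene_selection
#' @return For `glance()`: a one-row summary of the selection.
#' @method glance gene_selection
#' @export
glance.gene_selection <- function(x, ...) {
  tibble(
    method = x$method,
    fitness = x$fitness,
    accuracy_inner = x$accuracy_inner,
    redundancy = x$penalty,
    n_selected = x$n_selected,
    n_genes = x$n_genes,
    selected_fraction = x$n_selected / x$n_genes,
    n_evals = x$n_evals,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a 0.632+ error estimate
#'
#' @param x An `error_632` from [bootstrap_632plus()].
#' @param ... Unused.
#' @return A tibble with one row per error estimate (`estimate`, `value`).
#' @method tidy error_632
#' @export
tidy.error_632 <- function(x, ...) {
  tibble(
    estimate = c("resubstitution", "leave_one_out_bootstrap", "err_632plus"),
    value = c(x$err_resub, x$err_loo_boot, x$err_632plus)
  )
}

#' @rdname tidy.error_632
#' @return For `glance()`: the full estimate with diagnostics, one row.
#' @method glance error_632
#' @export
glance.error_632 <- function(x, ...) {
  tibble(
    err_resub = x$err_resub, err_loo_boot = x$err_loo_boot,
    err_632plus = x$err_632plus, w_blend = x$w_blend,
    R_overfit = x$R_overfit, gamma_noinfo = x$gamma_noinfo,
    B = x$B, n_excluded = x$n_excluded
  )
}

#' Convergence plot of an optimization run
#'
#' Best fitness per iteration; exploration and exploitation phases are
#' distinguished by colour.
#'
#' @param object An `epo_result` or `gene_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epo_result
#' @export
autoplot.epo_result <- function(object, ...) {
  h <- object$history
  ggplot(h, aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_step(color = "grey40") +
    geom_point(aes(color = .data$phase), size = 1.2) +
    labs(x = "Iteration", y = "Best fitness", color = "Phase",
         title = "EPO convergence") +
    theme_minimal()
}

#' @rdname autoplot.epo_result
#' @method autoplot gene_selection
#' @export
autoplot.gene_selection <- function(object, ...) {
  h <- object$history
  ggplot(h, aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_step(color = "grey40") +
    geom_point(aes(color = .data$phase), size = 1.2) +
    labs(x = "Iteration", y = "Best fitness", color = "Phase",
         title = sprintf("Gene selection convergence (%s)", object$method)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
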