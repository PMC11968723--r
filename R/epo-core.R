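#' Configure the Eagle Prey Optimization (EPO) optimizer
#'
#' Collects every hyperparameter of the continuous EPO search into a single
#' validated object. The optimizer mimics an eagle's hunt: a broad survey of
#' the search space (expanded exploration), a tightening spiral around
#' promising regions (narrowed exploration with Levy-flight jumps), and a
#' final swoop (exploitation). Early iterations use the exploration rules,
#' late iterations the exploitation rules; `phase_split` sets the boundary.
#'
#' @param n_pop Population size (number of candidate solutions), at least 2.
#' @param n_iter Number of iterations of the main loop (0 evaluates only the
#'   initial population).
#' @param alpha Exploding learning factor in (0, 1) scaling the pull towards
#'   the population mean during search-space selection.
#' @param gamma Exploration parameter in (0, 1) used by the expanded
#'   exploration and narrowed exploitation rules.
#' @param b Levy exponent (> 1) of the heavy-tailed flight distribution;
#'   the conventional value is 1.5.
#' @param search_cycle Spiral search-cycle parameter in (0, 5).
#' @param rotation_a Spiral rotation parameter in (2, 10).
#' @param w_max,w_min Endpoints of the linear adaptive exploration-factor
#'   schedule (defaults 0.9 and 0.4). The factor is recorded per iteration as
#'   a diagnostic of the exploration/exploitation balance.
#' @param phase_split Fraction of iterations spent in the exploration phase,
#'   in (0, 1); default 2/3.
#' @param seed Integer seed making the whole run reproducible, or `NULL`.
#'
#' @return An object of class `epo_config` (a named list).
#' @examples
#' cfg <- epo_config(n_pop = 10, n_iter = 20, seed = 1)
#' cfg$phase_split
#' @export
epo_config <- function(n_pop = 30, n_iter = 100, alpha = 0.5, gamma = 0.5,
                       b = 1.5, search_cycle = 2.5, rotation_a = 6,
                       w_max = 0.9, w_min = 0.4, phase_split = 2 / 3,
                       seed = NULL) {
  check_number(n_pop, "n_pop", lower = 2, integer = TRUE)
  check_number(n_iter, "n_iter", lower = 0, integer = TRUE)
  check_number(alpha, "alpha", 0, 1, open = TRUE)
  check_number(gamma, "gamma", 0, 1, open = TRUE)
  check_number(b, "b", lower = 1, open = TRUE)
  check_number(search_cycle, "search_cycle", 0, 5, open = TRUE)
  check_number(rotation_a, "rotation_a", 2, 10, open = TRUE)
  check_number(w_max, "w_max", lower = 0, open = TRUE)
  check_number(w_min, "w_min", lower = 0, open = TRUE)
  if (w_min > w_max) abort("`w_min` must not exceed `w_max`.")
  check_number(phase_split, "phase_split", 0, 1, open = TRUE)
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      n_pop = as.integer(n_pop), n_iter = as.integer(n_iter),
      alpha = alpha, gamma = gamma, b = b,
      search_cycle = search_cycle, rotation_a = rotation_a,
      w_max = w_max, w_min = w_min, phase_split = phase_split,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "epo_config"
  )
}

#' @export
print.epo_config <- function(x, ...) {
  cat("<epo_config>\n")
  cat(sprintf("  population %d, iterations %d (explore first %.0f%%)\n",
              x$n_pop, x$n_iter, 100 * x$phase_split))
  cat(sprintf("  alpha %.3g, gamma %.3g, Levy b %.3g, SC %.3g, a %.3g\n",
              x$alpha, x$gamma, x$b, x$search_cycle, x$rotation_a))
  cat(sprintf("  exploration factor %.2f -> %.2f, seed %s\n",
              x$w_max, x$w_min,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

#' Initialize an EPO population uniformly within bounds
#'
#' Draws an `n_pop` x `m` matrix of starting positions, each coordinate
#' uniform in its `[lower, upper]` interval. Uses the current RNG state;
#' seed beforehand (or via [run_epo()]) for reproducibility.
#'
#' @param n_pop Number of candidates (rows), at least 2.
#' @param m Problem dimension (columns), at least 1.
#' @param lower,upper Scalar or length-`m` finite bounds.
#' @return A numeric `n_pop` x `m` matrix.
#' @examples
#' set.seed(1)
#' init_population(5, 3, -1, 1)
#' @export
init_population <- function(n_pop, m, lower, upper) {
  check_number(n_pop, "n_pop", lower = 2, integer = TRUE)
  check_number(m, "m", lower = 1, integer = TRUE)
  lower <- rep_len(lower, m)
  upper <- rep_len(upper, m)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    abort("Bounds must be finite.")
  }
  if (any(lower > upper)) abort("`lower` must not exceed `upper`.")
  pos <- matrix(stats::runif(n_pop * m), nrow = n_pop)
  sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
}

#' Search-space selection update
#'
#' Moves a candidate towards the best-known hunting region:
#' `pos_best + alpha * beta * (pos_mean - pos_i)`, with `beta` a fresh
#' Uniform(0, 1) draw unless pinned.
#'
#' @param pos_best Best position found so far (length-`m` vector).
#' @param pos_mean Per-dimension mean of the current population.
#' @param pos_i The candidate's current position.
#' @param alpha Exploding learning factor in (0, 1).
#' @param beta Optional pinned random scalar; drawn Uniform(0, 1) if `NULL`.
#' @param lower,upper Optional bounds; the result is clamped when supplied.
#' @return A length-`m` numeric vector.
#' @examples
#' select_search_space(c(0, 0), c(2, 2), c(0, 0), alpha = 0.5, beta = 1)
#' @export
select_search_space <- function(pos_best, pos_mean, pos_i, alpha,
                                beta = NULL, lower = NULL, upper = NULL) {
  beta <- beta %||% stats::runif(1)
  out <- pos_best + alpha * beta * (pos_mean - pos_i)
  if (!is.null(lower)) out <- clamp(out, lower, upper)
  out
}

#' Expanded exploration update
#'
#' The wide spiral survey of the selected region:
#' `pos_best * gamma + (pos_mean - pos_best) * beta`.
#'
#' @inheritParams select_search_space
#' @param gamma Exploration parameter in (0, 1).
#' @return A length-`m` numeric vector.
#' @examples
#' expanded_exploration(c(4), c(2), gamma = 0.5, beta = 0.5)
#' @export
expanded_exploration <- function(pos_best, pos_mean, gamma,
                                 beta = NULL, lower = NULL, upper = NULL) {
  beta <- beta %||% stats::runif(1)
  out <- pos_best * gamma + (pos_mean - pos_best) * beta
  if (!is.null(lower)) out <- clamp(out, lower, upper)
  out
}

#' Levy-flight scale parameter
#'
#' The scale `omega` of the Mantegna Levy-flight sampler for exponent `b`:
#' `[Gamma(1 + b) sin(pi b / 2) / (Gamma((1 + b) / 2) b 2^((b - 1) / 2))]^(1/b)`.
#'
#' @param b Levy exponent, greater than 1.
#' @return A positive scalar.
#' @examples
#' levy_omega(1.5)
#' @export
levy_omega <- function(b) {
  check_number(b, "b", lower = 1, open = TRUE)
  (gamma(1 + b) * sin(pi * b / 2) /
     (gamma((1 + b) / 2) * b * 2^((b - 1) / 2)))^(1 / b)
}

#' Levy-flight step vector
#'
#' Heavy-tailed per-dimension steps `0.01 * u * omega / |v|^(1/b)` with
#' `u ~ Normal(0, omega^2)` and `v ~ Normal(0, 1)` (Mantegna sampler); any
#' `v` drawn exactly 0 is redrawn. Occasional long jumps let the search
#' escape local optima.
#'
#' @param m Dimension of the step vector.
#' @param b Levy exponent, greater than 1 (default 1.5).
#' @param u,v Optional pinned draws (scalars or length-`m` vectors) for
#'   deterministic traces; drawn internally when `NULL`.
#' @return A length-`m` numeric vector of steps.
#' @examples
#' set.seed(1)
#' levy_flight(5)
#' levy_flight(3, u = 0) # zero step
#' @export
levy_flight <- function(m, b = 1.5, u = NULL, v = NULL) {
  check_number(m, "m", lower = 1, integer = TRUE)
  om <- levy_omega(b)
  u <- rep_len(u %||% stats::rnorm(m, sd = om), m)
  if (is.null(v)) {
    v <- stats::rnorm(m)
    while (any(v == 0)) v[v == 0] <- stats::rnorm(sum(v == 0))
  } else {
    v <- rep_len(v, m)
    if (any(v == 0)) abort("Pinned `v` must be nonzero.")
  }
  0.01 * u / abs(v)^(1 / b)
}

#' Spiral coefficients of the eagle's flight path
#'
#' Per dimension `i`, draws `beta_i ~ Uniform(0, 1)` and sets the angle
#' `Theta_i = a * pi * beta_i` and radius `r_i = Theta_i + SC * beta_i`;
#' then `x_i = r_i sin(Theta_i)`, `y_i = r_i cos(Theta_i)`, each vector
#' normalized by its maximum absolute entry so `max|X| = max|Y| = 1`.
#' An all-zero `x` or `y` vector (a measure-zero angle coincidence)
#' triggers a redraw.
#'
#' @param m Dimension.
#' @param rotation_a Rotation parameter `a` in (2, 10).
#' @param search_cycle Search cycle `SC` in (0, 5).
#' @param beta Optional pinned draws (length `m`).
#' @return A list with numeric vectors `X` and `Y`.
#' @examples
#' set.seed(1)
#' sc <- spiral_coefficients(4, rotation_a = 6, search_cycle = 2.5)
#' max(abs(sc$X))
#' @export
spiral_coefficients <- function(m, rotation_a, search_cycle, beta = NULL) {
  check_number(m, "m", lower = 1, integer = TRUE)
  for (attempt in 1:100) {
    bb <- if (is.null(beta)) stats::runif(m) else rep_len(beta, m)
    theta <- rotation_a * pi * bb
    r <- theta + search_cycle * bb
    xr <- r * sin(theta)
    yr <- r * cos(theta)
    if (max(abs(xr)) > 0 && max(abs(yr)) > 0) {
      return(list(X = xr / max(abs(xr)), Y = yr / max(abs(yr))))
    }
    if (!is.null(beta)) abort("Pinned `beta` yields a degenerate spiral (all-zero axis); redraw required.")
  }
  abort("Spiral coefficient redraw failed 100 times.") # unreachable in practice
}

#' Narrowed exploration update
#'
#' Tightening spiral around the prey with a Levy jump:
#' `pos_best * F(D) + pos_rand + (Y - X) * beta`, where `F(D)` is a
#' Levy-flight step and `(X, Y)` are spiral coefficients.
#'
#' @inheritParams select_search_space
#' @param pos_rand Position of a uniformly chosen population member.
#' @param b Levy exponent.
#' @param rotation_a,search_cycle Spiral parameters.
#' @param fd Optional pinned Levy step vector.
#' @param spiral Optional pinned `list(X, Y)`.
#' @return A length-`m` numeric vector.
#' @export
narrowed_exploration <- function(pos_best, pos_rand, b = 1.5,
                                 rotation_a = 6, search_cycle = 2.5,
                                 fd = NULL, spiral = NULL, beta = NULL,
                                 lower = NULL, upper = NULL) {
  m <- length(pos_best)
  fd <- rep_len(fd %||% levy_flight(m, b), m)
  spiral <- spiral %||% spiral_coefficients(m, rotation_a, search_cycle)
  beta <- beta %||% stats::runif(1)
  out <- pos_best * fd + pos_rand + (spiral$Y - spiral$X) * beta
  if (!is.null(lower)) out <- clamp(out, lower, upper)
  out
}

#' Exploitation update (slow swoop)
#'
#' `0.1 * (pos_best - pos_mean) - 0.2 * beta * (pos_mean - pos_i) + pos_i`.
#' The constants 0.1 and 0.2 are fixed adjustment parameters of the
#' swooping phase.
#'
#' @inheritParams select_search_space
#' @return A length-`m` numeric vector.
#' @examples
#' exploitation(10, 0, 0, beta = 1)
#' @export
exploitation <- function(pos_best, pos_mean, pos_i, beta = NULL,
                         lower = NULL, upper = NULL) {
  beta <- beta %||% stats::runif(1)
  out <- 0.1 * (pos_best - pos_mean) - 0.2 * beta * (pos_mean - pos_i) + pos_i
  if (!is.null(lower)) out <- clamp(out, lower, upper)
  out
}

#' Narrowed exploitation update (forced swoop)
#'
#' `QF(t) * pos_best - 2 beta * pos_i - 2 gamma * F(D) + 2 beta` with the
#' quality function `QF(t) = t^((2 beta - 1) / (1 - n_iter)^2)`, which stays
#' in (0, 1] for `t >= 1` and sharpens the late-stage hunt.
#'
#' @inheritParams narrowed_exploration
#' @param pos_i The candidate's current position.
#' @param t Current iteration, at least 1.
#' @param n_iter Total number of iterations (> 1 for a defined exponent).
#' @param gamma Exploration parameter in (0, 1).
#' @return A length-`m` numeric vector.
#' @export
narrowed_exploitation <- function(pos_best, pos_i, t, n_iter, gamma,
                                  b = 1.5, fd = NULL, beta = NULL,
                                  lower = NULL, upper = NULL) {
  check_number(t, "t", lower = 1)
  m <- length(pos_best)
  beta <- beta %||% stats::runif(1)
  fd <- rep_len(fd %||% levy_flight(m, b), m)
  qf <- t^((2 * beta - 1) / (1 - n_iter)^2)
  out <- qf * pos_best - 2 * beta * pos_i - 2 * gamma * fd + 2 * beta
  if (!is.null(lower)) out <- clamp(out, lower, upper)
  out
}

#' Adaptive exploration-factor schedule
#'
#' Linear decay `w_max - (w_max - w_min) * t / n_iter` from `w_max` at
#' `t = 0` to `w_min` at `t = n_iter`, shifting the search from exploration
#' to exploitation over the run.
#'
#' @param t Current iteration in `[0, n_iter]`.
#' @param n_iter Total iterations (positive).
#' @param w_max,w_min Initial and final factor values.
#' @return The exploration factor at iteration `t`.
#' @examples
#' exploration_factor(0, 100)    # 0.9
#' exploration_factor(100, 100)  # 0.4
#' @export
exploration_factor <- function(t, n_iter, w_max = 0.9, w_min = 0.4) {
  if (any(n_iter <= 0)) abort("`n_iter` must be positive.")
  w_max - (w_max - w_min) * t / n_iter
}

#' Run the Eagle Prey Optimization loop
#'
#' Maximizes `objective` over a box-bounded continuous space. The run
#' initializes a uniform population, refines it once with the search-space
#' selection rule, then iterates: during the exploration phase
#' (`t <= phase_split * n_iter`) each candidate moves by expanded or
#' narrowed exploration (equal probability); afterwards by the plain or
#' narrowed exploitation rule. Replacement is greedy — a move is kept only
#' if it improves the candidate's fitness — so the best fitness history is
#' non-decreasing. All positions are clamped to the bounds after every move.
#'
#' @param objective Function mapping a length-`n_dim` numeric position to a
#'   finite scalar fitness (maximized).
#' @param n_dim Problem dimension.
#' @param lower,upper Scalar or per-dimension finite bounds.
#' @param config An [epo_config()].
#' @param seed Integer seed (defaults to `config$seed`); fixes the whole
#'   trajectory bit-for-bit.
#' @param accept_hook Optional function `(position, fitness, t) ->
#'   list(position, fitness) | NULL` called once per candidate per iteration
#'   on the candidate's retained (post-acceptance) state; if it returns an
#'   improved candidate (it must evaluate the objective itself), that
#'   candidate is adopted greedily. Used by [select_genes()] for the
#'   adaptive mask mutation.
#' @return An object of class `epo_result`: best position and fitness, the
#'   per-iteration history (a tibble with `iteration`, `best_fitness`,
#'   `explore_factor`, `phase`), final population, evaluation count, config.
#' @examples
#' sphere <- function(x) -sum(x^2)
#' res <- run_epo(sphere, n_dim = 3, lower = -5, upper = 5,
#'                config = epo_config(n_pop = 15, n_iter = 30, seed = 1))
#' res$best_fitness
#' @export
run_epo <- function(objective, n_dim, lower = -1, upper = 1,
                    config = epo_config(), seed = config$seed,
                    accept_hook = NULL) {
  stopifnot(is.function(objective))
  check_number(n_dim, "n_dim", lower = 1, integer = TRUE)
  lower <- rep_len(lower, n_dim)
  upper <- rep_len(upper, n_dim)
  n_evals <- 0L
  eval_obj <- function(p) {
    n_evals <<- n_evals + 1L
    f <- objective(p)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      abort("`objective` returned a non-finite value.")
    }
    f
  }

  run <- function() {
    pos <- init_population(config$n_pop, n_dim, lower, upper)
    fit <- apply(pos, 1, eval_obj)
    best_i <- which.max(fit)
    best_pos <- pos[best_i, ]
    best_fit <- fit[best_i]
    t_explore <- config$phase_split * config$n_iter

    adopt <- function(i, cand, f) {
      pos[i, ] <<- cand
      fit[i] <<- f
      if (f > best_fit) {
        best_fit <<- f
        best_pos <<- cand
      }
    }
    accept <- function(i, cand, t) {
      f <- eval_obj(cand)
      if (f > fit[i]) adopt(i, cand, f)
      if (!is.null(accept_hook)) {
        improved <- accept_hook(pos[i, ], fit[i], t)
        if (!is.null(improved) && improved$fitness > fit[i]) {
          adopt(i, improved$position, improved$fitness)
        }
      }
    }

    history <- vector("list", config$n_iter + 1L)
    history[[1]] <- list(iteration = 0L, best_fitness = best_fit,
                         explore_factor = config$w_max, phase = "init")

    if (config$n_iter >= 1L) {
      # one refinement pass with the search-space selection rule
      pos_mean <- colMeans(pos)
      for (i in seq_len(config$n_pop)) {
        cand <- select_search_space(best_pos, pos_mean, pos[i, ],
                                    config$alpha, lower = lower, upper = upper)
        accept(i, cand, 0L)
      }
      for (t in seq_len(config$n_iter)) {
        pos_mean <- colMeans(pos)
        exploring <- t <= t_explore
        for (i in seq_len(config$n_pop)) {
          coin <- stats::runif(1)
          cand <- if (exploring) {
            if (coin < 0.5) {
              expanded_exploration(best_pos, pos_mean, config$gamma,
                                   lower = lower, upper = upper)
            } else {
              j <- sample.int(config$n_pop, 1)
              narrowed_exploration(best_pos, pos[j, ], b = config$b,
                                   rotation_a = config$rotation_a,
                                   search_cycle = config$search_cycle,
                                   lower = lower, upper = upper)
            }
          } else {
            if (coin < 0.5) {
              exploitation(best_pos, pos_mean, pos[i, ],
                           lower = lower, upper = upper)
            } else {
              narrowed_exploitation(best_pos, pos[i, ], t, config$n_iter,
                                    config$gamma, b = config$b,
                                    lower = lower, upper = upper)
            }
          }
          accept(i, cand, t)
        }
        history[[t + 1L]] <- list(
          iteration = t, best_fitness = best_fit,
          explore_factor = exploration_factor(t, config$n_iter,
                                              config$w_max, config$w_min),
          phase = if (exploring) "explore" else "exploit"
        )
      }
    }
    list(pos = pos, fit = fit, best_pos = best_pos, best_fit = best_fit,
         history = dplyr::bind_rows(history[!vapply(history, is.null, TRUE)]))
  }

  out <- with_seed(seed, run())
  structure(
    list(
      best_position = out$best_pos,
      best_fitness = out$best_fit,
      history = out$history,
      population = out$pos,
      population_fitness = out$fit,
      n_evals = n_evals,
      config = config,
      seed = seed,
      lower = lower,
      upper = upper
    ),
    class = "epo_result"
  )
}

#' @export
print.epo_result <- function(x, ...) {
  cat("<epo_result>\n")
  cat(sprintf("  dimension %d, population %d, iterations %d\n",
              length(x$best_position), x$config$n_pop, x$config$n_iter))
  cat(sprintf("  best fitness %.6g after %d objective evaluations\n",
              x$best_fitness, x$n_evals))
  invisible(x)
}
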