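test_that("population initialization respects bounds, seed and uniformity", {
  # degenerate bounds force a unique point
  set.seed(1)
  expect_equal(init_population(3, 2, 0, 0), matrix(0, 3, 2))

  # identical seed, identical matrix
  a <- withr::with_seed(1, init_population(30, 10, -2, 2))
  b <- withr::with_seed(1, init_population(30, 10, -2, 2))
  expect_identical(a, b)
  expect_true(all(a >= -2 & a <= 2))

  # law of large numbers against the uniform sampling model
  big <- withr::with_seed(7, init_population(1000, 1, -1, 1))
  expect_lt(abs(mean(big)), 0.05)

  expect_error(init_population(1, 2, 0, 1), "n_pop")
  expect_error(init_population(3, 2, -Inf, 1), "finite")
})

test_that("search-space selection follows its update equation", {
  v <- c(1.5, -2)
  # zero displacement when mean equals the candidate
  expect_equal(select_search_space(v, v, v, alpha = 0.7, beta = 0.3), v)
  # alpha = 0 collapses to the best position
  expect_equal(select_search_space(c(1, 2), c(9, 9), c(0, 0), alpha = 0,
                                   beta = 0.9), c(1, 2))
  # pinned hand evaluation
  expect_equal(
    select_search_space(c(0, 0), c(2, 2), c(0, 0), alpha = 0.5, beta = 1),
    c(1, 1)
  )
})

test_that("expanded exploration follows its update equation", {
  v <- c(2, 3)
  expect_equal(expanded_exploration(v, v, gamma = 1, beta = 0.4), v)
  # gamma = 0, beta = 1 isolates the mean-minus-best term
  expect_equal(expanded_exploration(c(1, 1), c(4, 0), gamma = 0, beta = 1),
               c(3, -1))
  # hand evaluation: 4 * 0.5 + (2 - 4) * 0.5 = 1
  expect_equal(expanded_exploration(4, 2, gamma = 0.5, beta = 0.5), 1)
})

test_that("Levy scale matches an independent gamma-function evaluation", {
  b <- 1.5
  # independent evaluation through log-gamma to avoid shared rounding paths
  log_num <- lgamma(1 + b) + log(sin(pi * b / 2))
  log_den <- lgamma((1 + b) / 2) + log(b) + ((b - 1) / 2) * log(2)
  omega_ref <- exp((log_num - log_den) / b)
  expect_equal(levy_omega(1.5), omega_ref, tolerance = 1e-12)
  expect_error(levy_omega(1), "b")
})

test_that("Levy flight is linear in u and heavy-tailed", {
  expect_equal(levy_flight(4, u = 0), rep(0, 4))
  expect_error(levy_flight(3, v = 0), "nonzero")

  # Monte-Carlo oracle: excess kurtosis far beyond Gaussian
  steps <- withr::with_seed(11, levy_flight(1e5))
  kurt <- mean((steps - mean(steps))^4) / stats::var(steps)^2
  expect_gt(kurt, 10)
})

test_that("spiral coefficients are max-normalized and respect pinned draws", {
  for (s in 1:20) {
    sc <- withr::with_seed(s, spiral_coefficients(7, rotation_a = 6,
                                                  search_cycle = 2.5))
    expect_equal(max(abs(sc$X)), 1)
    expect_equal(max(abs(sc$Y)), 1)
  }
  # single entry normalizes to +/-1
  sc1 <- withr::with_seed(1, spiral_coefficients(1, 6, 2.5))
  expect_equal(abs(sc1$X), 1)
  expect_equal(abs(sc1$Y), 1)
  # degenerate pinned draw (zero angle and radius) demands a redraw
  expect_error(spiral_coefficients(1, rotation_a = 2, search_cycle = 0,
                                   beta = 0),
               "degenerate")
})

test_that("narrowed exploration combines Levy step, random mate and spiral", {
  # F(D) = 0 and beta = 0 isolate the random member
  expect_equal(
    narrowed_exploration(c(5, 5), c(1, 2), fd = 0,
                         spiral = list(X = c(1, 1), Y = c(0, 0)), beta = 0),
    c(1, 2)
  )
  # pinned hand evaluation: 2 * 0.5 + 1 + 1 * 0.5 = 2.5
  expect_equal(
    narrowed_exploration(2, 1, fd = 0.5,
                         spiral = list(X = 0, Y = 1), beta = 0.5),
    2.5
  )
  # clamping contract
  out <- withr::with_seed(3, narrowed_exploration(c(4, 4), c(4, -4),
                                                  lower = -4, upper = 4))
  expect_true(all(out >= -4 & out <= 4))
})

test_that("exploitation rules follow their update equations", {
  v <- c(0.5, -1)
  expect_equal(exploitation(v, v, v, beta = 0.8), v)
  # hand evaluation: 0.1 * 10 - 0 + 0 = 1
  expect_equal(exploitation(10, 0, 0, beta = 1), 1)
  # beta = 0 isolates the best-vs-mean drift
  expect_equal(exploitation(c(2, 2), c(1, 1), c(0, 0), beta = 0),
               c(0.1, 0.1))

  # narrowed exploitation, beta pinned at 0.5: QF = 1 and the update
  # reduces to best - pos - 2 * gamma * F(D) + 1
  expect_equal(
    narrowed_exploitation(3, 1, t = 5, n_iter = 10, gamma = 0.5,
                          fd = 0.4, beta = 0.5),
    3 - 1 - 2 * 0.5 * 0.4 + 1
  )
  expect_equal(
    narrowed_exploitation(3, 1, t = 5, n_iter = 10, gamma = 0.5,
                          fd = 0, beta = 0.5),
    3
  )
  expect_error(narrowed_exploitation(3, 1, t = 0, n_iter = 10, gamma = 0.5),
               "t")
})

test_that("exploration factor is the linear schedule with exact endpoints", {
  expect_equal(exploration_factor(0, 100), 0.9)
  expect_equal(exploration_factor(100, 100), 0.4)
  expect_equal(exploration_factor(50, 100), 0.65)
  expect_error(exploration_factor(1, 0), "positive")
})

test_that("run_epo is elitist, bounded and deterministic", {
  sphere <- function(x) -sum(x^2)
  cfg <- epo_config(n_pop = 12, n_iter = 40, seed = 3)
  r1 <- run_epo(sphere, 4, -5, 5, cfg)
  r2 <- run_epo(sphere, 4, -5, 5, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)
  expect_false(is.unsorted(r1$history$best_fitness))
  expect_true(all(r1$population >= -5 & r1$population <= 5))
  expect_true(all(abs(r1$best_position) <= 5))

  # constant objective: nothing to optimize
  flat <- run_epo(function(x) 1, 3, -1, 1, epo_config(n_pop = 5, n_iter = 10,
                                                      seed = 1))
  expect_true(all(flat$history$best_fitness == 1))

  # non-finite objective aborts with a diagnostic
  expect_error(
    run_epo(function(x) NaN, 2, -1, 1, epo_config(n_pop = 5, n_iter = 2,
                                                  seed = 1)),
    "non-finite"
  )
})

test_that("run_epo converges on the sphere benchmark", {
  sphere <- function(x) -sum(x^2)
  best <- vapply(1:5, function(s) {
    run_epo(sphere, 5, -5, 5, epo_config(n_pop = 30, n_iter = 100,
                                         seed = s))$best_fitness
  }, numeric(1))
  expect_true(all(best >= -0.1))
})

test_that("epo_config validates its hyperparameter ranges", {
  expect_error(epo_config(alpha = 1.5), "alpha")
  expect_error(epo_config(search_cycle = 5), "search_cycle")
  expect_error(epo_config(rotation_a = 1), "rotation_a")
  expect_error(epo_config(w_max = 0.3, w_min = 0.5), "w_min")
  expect_error(epo_config(n_pop = 1), "n_pop")
  expect_s3_class(epo_config(seed = 5), "epo_config")
})

test_that("tidiers expose the optimization history", {
  r <- run_epo(function(x) -sum(x^2), 2, -1, 1,
               epo_config(n_pop = 5, n_iter = 8, seed = 2))
  h <- generics::tidy(r)
  expect_s3_class(h, "tbl_df")
  expect_equal(nrow(h), 9) # init + 8 iterations
  g <- generics::glance(r)
  expect_equal(g$best_fitness, r$best_fitness)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
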