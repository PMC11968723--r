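test_that("binarization thresholds the sigmoid and repairs empty masks", {
  expect_equal(binarize(rep(10, 5)), rep(TRUE, 5))
  # all strongly negative: argmax repair keeps exactly one gene
  m <- binarize(c(-10, -12, -11))
  expect_equal(m, c(TRUE, FALSE, FALSE))
  # sigmoid(0) = 0.5 is not strictly greater than the threshold
  expect_equal(binarize(c(-1, 0, 1)), c(FALSE, FALSE, TRUE))
  expect_error(binarize(c(1, NA)), "finite")
})

test_that("redundancy penalty measures mean absolute pairwise correlation", {
  d <- tiny_expression(n = 50, p = 4, seed = 2)
  # single selected gene has no pairs
  expect_equal(redundancy_penalty(d, c(TRUE, FALSE, FALSE, FALSE)), 0)

  # two exact copies correlate perfectly
  dup <- tibble::tibble(a = rnorm(30), class = factor(rep(c("x", "y"), 15)))
  dup$b <- dup$a
  expect_equal(redundancy_penalty(dup, c(TRUE, TRUE)), 1)

  # Monte-Carlo null: independent standard normals at n = 500
  null <- withr::with_seed(5, tibble::tibble(
    a = rnorm(500), b = rnorm(500), class = factor(rep(c("x", "y"), 250))
  ))
  expect_lt(redundancy_penalty(null, c(TRUE, TRUE)), 0.15)

  # zero-variance gene: correlations treated as 0, with a warning
  zv <- tibble::tibble(a = rnorm(20), b = rep(1, 20), cc = rnorm(20),
                       class = factor(rep(c("x", "y"), 10)))
  expect_warning(p <- redundancy_penalty(zv, rep(TRUE, 3)), "zero-variance")
  expect_gte(p, 0)
  expect_error(redundancy_penalty(zv, rep(FALSE, 3)), "no genes")
})

test_that("composite fitness combines accuracy, sparsity and redundancy", {
  # hand arithmetic: 0.9 * 0.95 + 0.1 * 0.95 - 0.1 * 0.2 = 0.93
  expect_equal(combine_fitness(0.95, 100, 2000, 0.2), 0.93)
  # full mask: sparsity term contributes nothing
  cfg5 <- fitness_config(alpha_weight = 0.5)
  expect_equal(combine_fitness(0.8, 50, 50, 0, cfg5), 0.4)
  # alpha = 1, W = 0 collapses to accuracy
  cfg10 <- fitness_config(alpha_weight = 1, redundancy_weight = 0)
  expect_equal(combine_fitness(0.77, 3, 10, 0.9, cfg10), 0.77)

  # fitness bound and strict monotonicity in subset size
  cfg <- fitness_config()
  for (ns in 1:9) {
    expect_gt(combine_fitness(0.5, ns, 10, 0.5, cfg),
              combine_fitness(0.5, ns + 1, 10, 0.5, cfg))
  }
  expect_lte(combine_fitness(1, 1, 10, 0, cfg), 1)
  expect_gte(combine_fitness(0, 10, 10, 1, cfg),
             -cfg$redundancy_weight)
})

test_that("mask fitness reproduces from its seed and collapses to accuracy", {
  d <- tiny_expression(seed = 3)
  mask <- rep(c(TRUE, FALSE), 5)
  f1 <- mask_fitness(d, mask, classifier_spec("knn"), seed = 9)
  f2 <- mask_fitness(d, mask, classifier_spec("knn"), seed = 9)
  expect_identical(f1, f2)

  cfg <- fitness_config(alpha_weight = 1, redundancy_weight = 0)
  f <- mask_fitness(d, mask, classifier_spec("knn"), cfg, seed = 9)
  expect_equal(as.numeric(f), attr(f, "accuracy"))
})

test_that("adaptive mutation follows the decaying flip schedule", {
  mask <- rep(c(TRUE, FALSE), 500)
  expect_identical(mutate_mask(mask, 0, 100, rate = 0), mask)
  # certain flip complements the mask
  expect_identical(withr::with_seed(1, mutate_mask(mask, 0, 100, rate = 1)),
                   !mask)
  # full complement of an all-TRUE mask is empty: repair selects one gene
  repaired <- withr::with_seed(1, mutate_mask(rep(TRUE, 6), 0, 100, rate = 1))
  expect_equal(sum(repaired), 1)

  # binomial concentration at rate 0.1 over 10^4 bits
  big <- rep(TRUE, 1e4)
  flipped <- withr::with_seed(2, mean(!mutate_mask(big, 0, 100,
                                                   fitness_config())))
  expect_lt(abs(flipped - 0.1), 0.01)

  # schedule endpoints: rate_max at t = 0, rate_min at t = n_iter
  cfg <- fitness_config(mutation_rate_max = 0.5, mutation_rate_min = 0.1)
  fr0 <- withr::with_seed(3, mean(xor(big, mutate_mask(big, 0, 10, cfg))))
  frT <- withr::with_seed(4, mean(xor(big, mutate_mask(big, 10, 10, cfg))))
  expect_lt(abs(fr0 - 0.5), 0.02)
  expect_lt(abs(frT - 0.1), 0.02)
})

test_that("exhaustive search enumerates every non-empty subset", {
  d <- tiny_expression(n = 30, p = 8, k_info = 2, seed = 4)
  oracle <- exhaustive_search(d, classifier_spec("knn"), seed = 1)
  expect_equal(oracle$n_evals, 255) # 2^8 - 1
  expect_gte(oracle$n_selected, 1)

  # single gene: only one subset
  d1 <- d[c("g0001", "class")]
  o1 <- exhaustive_search(d1, classifier_spec("knn"), seed = 1)
  expect_equal(o1$n_evals, 1)
  expect_equal(unname(o1$mask), TRUE)

  big <- tiny_expression(n = 20, p = 21, k_info = 2, seed = 1)
  expect_error(exhaustive_search(big), "20 genes")
})

test_that("the oracle dominates EPO and EPO gets close on small instances", {
  d <- tiny_expression(n = 40, p = 8, k_info = 2, seed = 5)
  clf <- classifier_spec("knn")
  hits <- 0
  for (s in 1:3) {
    oracle <- exhaustive_search(d, clf, seed = s)
    sel <- select_genes(d, clf, epo_config(n_pop = 15, n_iter = 30, seed = s))
    expect_gte(oracle$fitness, sel$fitness - 1e-12)
    if (sel$fitness >= 0.99 * oracle$fitness) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("gene selection is reproducible and well-formed", {
  d <- tiny_expression(n = 40, p = 12, seed = 6)
  cfg <- epo_config(n_pop = 8, n_iter = 12, seed = 21)
  s1 <- select_genes(d, epo = cfg)
  s2 <- select_genes(d, epo = cfg)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$fitness, s2$fitness)
  expect_identical(s1$history, s2$history)
  expect_gte(s1$n_selected, 1)
  expect_equal(s1$n_selected, sum(s1$mask))
  expect_equal(s1$genes, names(s1$mask)[s1$mask])

  # the recorded fitness reproduces from the recorded mask and seed
  refit <- mask_fitness(d, unname(s1$mask), classifier_spec("knn"),
                        fitness_config(),
                        seed = eposelect:::child_seed(21, 1))
  expect_equal(s1$fitness, as.numeric(refit))

  # n_iter = 0: the best of the initial population, no updates
  s0 <- select_genes(d, epo = epo_config(n_pop = 8, n_iter = 0, seed = 21))
  expect_equal(s0$n_evals, 8L)
  expect_equal(nrow(s0$history), 1L)
})

test_that("tidiers summarize gene selections", {
  d <- tiny_expression(n = 30, p = 6, seed = 7)
  sel <- select_genes(d, epo = epo_config(n_pop = 6, n_iter = 5, seed = 2))
  td <- generics::tidy(sel)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$selected), sel$n_selected)
  expect_equal(td$gene, paste0("g000", 1:6))
  g <- generics::glance(sel)
  expect_equal(g$n_selected, sel$n_selected)
  expect_equal(g$selected_fraction, sel$n_selected / 6)
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
})

test_that("random search respects its budget and finds a valid mask", {
  d <- tiny_expression(n = 30, p = 10, seed = 8)
  r <- random_search(d, n_evals = 50, seed = 3)
  expect_equal(r$n_evals, 50L)
  expect_gte(r$n_selected, 1)
  expect_false(is.unsorted(r$history$best_fitness))
  r2 <- random_search(d, n_evals = 50, seed = 3)
  expect_identical(r$mask, r2$mask)
})
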