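# Shared fixtures, all generated in code.

# Two well-separated Gaussian blobs in 2 dimensions.
make_blobs <- function(n_per_class = 30, shift = 4, seed = 1) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n_per_class * 2), ncol = 2)
    x2 <- matrix(rnorm(n_per_class * 2), ncol = 2) + shift
    out <- tibble::tibble(
      f1 = c(x1[, 1], x2[, 1]),
      f2 = c(x1[, 2], x2[, 2]),
      class = factor(rep(c("a", "b"), each = n_per_class))
    )
    out
  })
}

# Small planted-signal expression set used across modules.
tiny_expression <- function(n = 40, p = 10, k_info = 3, seed = 1) {
  generate_expression(synthetic_spec(
    n_instances = n, n_genes = p, n_informative = k_info, n_redundant = 0,
    effect_size = 2, seed = seed
  ))
}
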