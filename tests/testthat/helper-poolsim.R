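# Small configurations keep the unit tests fast; the acceptance tests use
# the full-size study conditions.

tiny_cfg <- function(...) {
  args <- list(n_per_class = 10, n_features = 60, n_de_genes = 5,
               n_patterns = 5)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# Two well-separated Gaussian clouds in two dimensions.
separable_toy <- function(n = 20, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), ncol = 2),
             matrix(rnorm(n * 2, mean = gap), ncol = 2))
  list(x = x, y = factor(rep(c("A", "B"), each = n)))
}

# XOR-style four-cluster layout: not linearly separable.
xor_toy <- function(n_per_cluster = 10, seed = 2) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  x <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(n_per_cluster * 2, sd = 0.3), ncol = 2), 2,
          centers[i, ], "+")))
  list(x = x, y = factor(rep(c("A", "A", "B", "B"), each = n_per_cluster)))
}
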