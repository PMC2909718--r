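test_that("background draws have the configured mean and spread", {
  cfg <- sim_config()
  set.seed(1)
  x <- draw_background(100, 1000, cfg)  # 1e5 draws
  mc_se <- 0.2 / sqrt(length(x))
  expect_lt(abs(mean(x) - 8), 3 * mc_se)
  expect_lt(abs(sd(x) - 0.2), 3 * 0.2 / sqrt(2 * length(x)))
  expect_equal(dim(draw_background(2, 3, cfg)), c(2L, 3L))
  expect_error(draw_background(0, 3, cfg), "positive")
})

test_that("background degenerates to a constant as bio_sd shrinks", {
  cfg <- sim_config(bio_sd = 1e-12)
  set.seed(1)
  x <- draw_background(5, 5, cfg)
  expect_equal(x, matrix(8, 5, 5), tolerance = 1e-9)
})

test_that("DE block: delta in range and class difference converges to it", {
  cfg <- sim_config(n_per_class = 10000, n_de_genes = 5, n_features = 5)
  set.seed(2)
  de <- simulate_de_block(cfg)
  expect_true(all(de$delta >= 0.1 & de$delta <= 0.5))
  n <- cfg$n_per_class
  diff <- colMeans(de$x[n + 1:n, ]) - colMeans(de$x[1:n, ])
  expect_true(all(abs(diff - de$delta) < 3 * 0.2 * sqrt(2 / n)))
})

test_that("null DE interval gives statistically indistinguishable classes", {
  cfg <- sim_config(n_per_class = 200, n_de_genes = 20, n_features = 20,
                    de_delta_interval = c(0, 0))
  set.seed(3)
  de <- simulate_de_block(cfg)
  expect_equal(de$delta, rep(0, 20))
  y <- rep(c("A", "B"), each = 200)
  p <- apply(de$x, 2, function(v) t.test(v ~ y, var.equal = TRUE)$p.value)
  expect_gt(min(p) * 20, 0.001)  # Bonferroni: no column signals
})

test_that("linear patterns obey the exact biological identities", {
  cfg <- sim_config()
  set.seed(4)
  pat <- simulate_pattern_block(cfg)
  n <- cfg$n_per_class
  for (j in seq_len(cfg$n_patterns)) {
    g1 <- pat$x[, pat$pairing$g1_col[j]]
    g2 <- pat$x[, pat$pairing$g2_col[j]]
    expect_equal(g2[1:n], 2 * g1[1:n])                    # class A: g2 = 2 g1
    expect_equal(g2[n + 1:n], 2 * g1[n + 1:n] + 0.4)      # class B: + delta
  }
})

test_that("expected class difference on the second pattern gene is delta", {
  cfg <- sim_config(n_per_class = 20000, n_patterns = 1, n_features = 2,
                    scenario = "LINEAR_ONLY")
  set.seed(5)
  pat <- simulate_pattern_block(cfg)
  n <- cfg$n_per_class
  g2 <- pat$x[, 2]
  est <- mean(g2[n + 1:n]) - mean(g2[1:n])
  expect_lt(abs(est - 0.4), 3 * 2 * 0.2 * sqrt(2 / n))
})

test_that("assembled datasets have the right composition per scenario", {
  for (sc in c("DE_ONLY", "LINEAR_ONLY", "COMBINED")) {
    ds <- simulate_dataset(sim_config(scenario = sc, seed = 6))
    expect_equal(dim(ds$Y), c(60L, 1000L))
    expect_equal(dim(ds$X), dim(ds$Y))
    expect_equal(as.vector(table(ds$labels)), c(30L, 30L))
    counts <- table(ds$truth$role)
    exp_inf <- c(DE_ONLY = 10, LINEAR_ONLY = 20, COMBINED = 30)[[sc]]
    expect_equal(sum(ds$truth$role != "background"), exp_inf)
    if (sc != "DE_ONLY") {
      expect_equal(unname(counts["pattern_g1"]), unname(counts["pattern_g2"]))
      g2 <- ds$truth[ds$truth$role == "pattern_g2", ]
      expect_equal(sort(unique(g2$pattern)), 1:10)  # each g2 paired once
    }
  }
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- sim_config(scenario = "COMBINED", seed = 99)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$Y, ds2$Y)
  expect_identical(ds1$truth, ds2$truth)
})

test_that("fixed gene-level params are honored by a matching dataset", {
  ds <- simulate_dataset(sim_config(scenario = "COMBINED", seed = 7))
  te <- simulate_dataset(ds$config, params = ds$params)
  expect_equal(te$truth$delta, ds$truth$delta)
  expect_false(identical(te$X, ds$X))  # new subjects
})

test_that("technical noise has the stated variance and a zero limit", {
  set.seed(8)
  x <- matrix(rnorm(1e5, 8, 0.2), 200)
  expect_identical(add_technical_noise(x, 0), x)
  for (s in c(0.2, 0.4)) {
    e <- add_technical_noise(x, s) - x
    expect_lt(abs(var(as.vector(e)) - s^2) / s^2, 0.03)
  }
  expect_error(add_technical_noise(x, -1), "non-negative")
})

test_that("background columns carry no class signal (uniform p-values)", {
  cfg <- sim_config(n_features = 1110, scenario = "DE_ONLY")
  ds <- simulate_dataset(cfg)
  bg <- ds$Y[, ds$truth$role == "background"]
  p <- poolsim:::col_ttest_p(bg, ds$labels)
  expect_gte(length(p), 1000)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_per_class = 1), "at least 2")
  expect_error(sim_config(n_features = 5), "exceed")
  expect_error(sim_config(bio_sd = 0), "positive")
  expect_error(sim_config(noise_sd = -0.1), "non-negative")
  expect_error(sim_config(de_delta_interval = c(-0.1, 0.5)), ">= 0")
  expect_error(sim_config(scenario = "NOPE"))
})
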