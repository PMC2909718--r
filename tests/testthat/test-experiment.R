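test_that("prediction error is the mismatch fraction", {
  expect_equal(prediction_error(c("A", "A"), c("A", "A")), 0)
  expect_equal(prediction_error(c("A", "A"), c("B", "B")), 1)
  pred <- rep("A", 60); truth <- rep("A", 60); truth[1:3] <- "B"
  expect_equal(prediction_error(pred, truth), 0.05)
  expect_error(prediction_error("A", c("A", "B")), "equal length")
  expect_error(prediction_error(character(0), character(0)), "at least one")
})

test_that("repetitions are reproducible and error granularity is 1/n_test", {
  cfg <- tiny_cfg()
  r1 <- run_repetition(cfg, 2, "tlda", rep_seed = 42)
  r2 <- run_repetition(cfg, 2, "tlda", rep_seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$error * 20 %% 1, 0)  # 20 test singles
})

test_that("a method's result does not depend on which other methods run", {
  cfg <- tiny_cfg()
  alone <- run_repetition(cfg, 1, "tlda", rep_seed = 7)
  paired <- run_repetition(cfg, 1, c("svml", "tlda"), rep_seed = 7)
  expect_equal(paired$error[paired$method == "tlda"], alone$error)
})

test_that("huge effects with no noise are perfectly classified", {
  cfg <- sim_config(n_per_class = 10, n_features = 30, n_de_genes = 10,
                    noise_sd = 0, de_delta_interval = c(5, 5),
                    scenario = "DE_ONLY")
  for (m in c("svml", "tlda")) {
    r <- run_repetition(cfg, 2, m, rep_seed = 1)
    expect_equal(r$error, 0, info = m)
  }
})

test_that("run_experiment assembles records and summaries coherently", {
  cfg <- tiny_cfg()
  ex <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
                       methods = "tlda", pool_sizes = c(1, 2), n_reps = 3,
                       base_seed = 1, cfg = cfg)
  expect_s3_class(ex, "pooling_experiment")
  expect_equal(nrow(ex$records), 6)
  set.seed(1)
  s <- summary(ex, n_boot = 200)
  expect_equal(nrow(s), 2)
  for (i in 1:2) {
    cell <- ex$records[ex$records$m_p == s$m_p[i], ]
    expect_equal(s$mean_error[i], mean(cell$error))
    expect_lte(s$ci_lower[i], s$mean_error[i])
    expect_gte(s$ci_upper[i], s$mean_error[i])
  }
  # degradation column: largest pool size over single-sample design
  expect_equal(unique(s$degradation),
               s$mean_error[s$m_p == 2] / s$mean_error[s$m_p == 1])
})

test_that("experiments are reproducible and resumable from checkpoints", {
  cfg <- tiny_cfg()
  dir <- withr::local_tempdir()
  ex1 <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
                        methods = "svml", pool_sizes = 2, n_reps = 2,
                        base_seed = 5, cfg = cfg, checkpoint_dir = dir)
  ex2 <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
                        methods = "svml", pool_sizes = 2, n_reps = 2,
                        base_seed = 5, cfg = cfg, checkpoint_dir = dir)
  expect_equal(ex1$records$error, ex2$records$error)
  ex3 <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
                        methods = "svml", pool_sizes = 2, n_reps = 2,
                        base_seed = 5, cfg = cfg)
  expect_equal(ex1$records$error, ex3$records$error)
})

test_that("bootstrap CI: degenerate, coverage of the mean, and width", {
  set.seed(1)
  expect_equal(unname(bootstrap_ci(rep(0.2, 10))), c(0.2, 0.2))
  errs <- rnorm(500, 0.2, 0.01)
  ci <- bootstrap_ci(errs, level = 0.95, n_boot = 2000)
  expect_lte(ci["lower"], mean(errs))
  expect_gte(ci["upper"], mean(errs))
  width <- ci["upper"] - ci["lower"]
  normal_width <- 2 * 1.96 * sd(errs) / sqrt(500)
  expect_lt(abs(width - normal_width) / normal_width, 0.15)
  expect_error(bootstrap_ci(0.5), "at least two")
  expect_error(bootstrap_ci(c(0.1, 0.2), level = 1.2), "in \\(0, 1\\)")
})

test_that("summary has one ordered row per grid cell", {
  cfg <- tiny_cfg()
  ex <- run_experiment(scenarios = c("DE_ONLY", "LINEAR_ONLY"),
                       noise_sds = c(0.2, 0.4), methods = c("svml", "tlda"),
                       pool_sizes = c(1, 5), n_reps = 2, base_seed = 3,
                       cfg = cfg)
  set.seed(2)
  s <- summary(ex, n_boot = 100)
  expect_equal(nrow(s), 2 * 2 * 2 * 2)
  expect_true(all(s$mean_error >= 0 & s$mean_error <= 1))
  ord <- order(s$scenario, s$noise_sd, s$method, s$m_p)
  expect_equal(ord, seq_len(nrow(s)))
})
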