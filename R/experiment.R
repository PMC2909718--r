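#' Prediction error: relative frequency of wrong classifications
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of mismatches in `[0, 1]` (a multiple of
#'   `1/length(truth)`).
#' @examples
#' prediction_error(c("A", "B", "B"), c("A", "A", "B"))
#' @export
prediction_error <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  if (length(truth) == 0L)
    stop("need at least one test sample", call. = FALSE)
  mean(as.character(predicted) != as.character(truth))
}

#' Run one simulation repetition: simulate, pool, train, test
#'
#' Generates a fresh training dataset, pools it at pool size `m_p`
#' (`m_p = 1` keeps the single-sample measured matrix), trains each requested
#' method on the (pooled) training set, generates a fresh single-sample test
#' dataset under the same conditions (same gene-level parameters, new
#' subjects), and returns the test prediction error per method.
#'
#' Training arrays (single samples or pools) carry technical noise at the
#' configured level; the independent test singles are evaluated at
#' `test_noise_sd`, which defaults to 0 — the benchmark's evaluation
#' protocol measures how well a signature learned from noisy (possibly
#' pooled) arrays recovers the underlying biological class structure of new
#' single samples. Set `test_noise_sd = cfg$noise_sd` for fully noisy test
#' measurements. All methods within a repetition share the same training
#' and test data (paired comparison); each method's own randomness (forest
#' growth, CV fold assignment) is re-seeded from `rep_seed` and the method
#' tag, so a method's result does not depend on which other methods run.
#'
#' @param cfg A [sim_config()] (its `seed` field is ignored here).
#' @param m_p Pool size for the training design.
#' @param methods Character vector of method tags (see
#'   [train_classifier()]).
#' @param rep_seed Integer seed making the repetition fully reproducible.
#' @param test_noise_sd Technical noise sd applied to the test measurements
#'   (default 0: tests on biological single-sample values).
#' @return Data frame with one row per method: `method`, `error`, `tuning`
#'   (a compact text summary of tuned hyperparameters).
#' @export
run_repetition <- function(cfg, m_p, methods = METHOD_TAGS, rep_seed = 1L,
                           test_noise_sd = 0) {
  methods <- match.arg(methods, METHOD_TAGS, several.ok = TRUE)
  cfg$seed <- NULL
  set.seed(derive_seed(rep_seed, "data"))
  train_ds <- simulate_dataset(cfg)
  if (m_p == 1L) {
    x_train <- train_ds$Y
    y_train <- train_ds$labels
  } else {
    pooled <- pooled_training_set(train_ds, m_p)
    x_train <- pooled$Y
    y_train <- pooled$labels
  }
  test_cfg <- cfg
  test_cfg$noise_sd <- test_noise_sd
  test_ds <- simulate_dataset(test_cfg, params = train_ds$params)
  out <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    m <- methods[i]
    set.seed(derive_seed(rep_seed, "method", m))
    model <- train_classifier(m, x_train, y_train)
    err <- prediction_error(predict(model, test_ds$Y), test_ds$labels)
    out[[i]] <- data.frame(method = m, error = err,
                           tuning = tuning_summary(model),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

tuning_summary <- function(model) {
  tune <- model$tuning
  switch(model$method,
         svml = sprintf("cost=%g", tune$cost),
         svmr = sprintf("gamma=%.3g", tune$gamma),
         rf = sprintf("ntree=%d;mtry=%d", tune$ntree, tune$mtry),
         pplsda = sprintf("ncomp=%d;gamma=%s", tune$ncomp,
                          paste(signif(tune$gamma, 3), collapse = "/")),
         tlda = sprintf("features=%s", paste(tune$selected, collapse = "/")))
}

#' Run the full repetition grid
#'
#' Executes `n_reps` independent repetitions for every combination of
#' scenario, noise level, and pool size, training all requested methods on
#' the shared training set of each repetition. Per-repetition seeds are
#' derived from `base_seed` and the cell coordinates, so any single cell (or
#' repetition) can be reproduced in isolation and cells can be computed in
#' any order. With `checkpoint_dir` set, each finished cell is written to a
#' CSV and complete cells are skipped on rerun.
#'
#' @param scenarios Character vector of scenario tags.
#' @param noise_sds Numeric vector of technical noise sds.
#' @param methods Character vector of method tags.
#' @param pool_sizes Integer vector of pool sizes (each must divide
#'   `n_per_class`).
#' @param n_reps Repetitions per cell.
#' @param base_seed Base seed for the whole experiment.
#' @param cfg Template [sim_config()]; its `scenario` and `noise_sd` fields
#'   are overridden cell by cell.
#' @param checkpoint_dir Optional directory for per-cell result CSVs.
#' @param test_noise_sd Technical noise sd for the test measurements (see
#'   [run_repetition()]; default 0).
#' @param verbose Print per-cell progress and timing (default `FALSE`).
#' @return Object of class `"pooling_experiment"`: list with `records` (long
#'   data frame: scenario, noise_sd, method, m_p, rep, error, tuning) and
#'   `base_seed`. Supports `print`, `summary`, and `plot`.
#' @examples
#' ex <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
#'                      methods = "tlda", pool_sizes = c(1, 2), n_reps = 3,
#'                      base_seed = 1,
#'                      cfg = sim_config(n_per_class = 10, n_features = 50))
#' summary(ex)
#' @export
run_experiment <- function(scenarios = c("DE_ONLY", "LINEAR_ONLY", "COMBINED"),
                           noise_sds = c(0.2, 0.4),
                           methods = METHOD_TAGS,
                           pool_sizes = c(1, 2, 3, 5),
                           n_reps = 500,
                           base_seed = 1,
                           cfg = sim_config(),
                           checkpoint_dir = NULL,
                           test_noise_sd = 0,
                           verbose = FALSE) {
  stopifnot(n_reps >= 1)
  methods <- match.arg(methods, METHOD_TAGS, several.ok = TRUE)
  for (m_p in pool_sizes)
    if (cfg$n_per_class %% m_p != 0L)
      stop("pool size ", m_p, " does not divide n_per_class = ",
           cfg$n_per_class, call. = FALSE)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  records <- list()
  for (sc in scenarios) for (ns in noise_sds) for (m_p in pool_sizes) {
    cell_tag <- sprintf("%s_n%s_m%d", sc, format(ns), m_p)
    cp_file <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0("cell_", cell_tag, ".csv")) else NULL
    if (!is.null(cp_file) && file.exists(cp_file)) {
      cell <- utils::read.csv(cp_file, stringsAsFactors = FALSE)
      if (all(methods %in% unique(cell$method)) &&
          max(cell$rep) >= n_reps) {
        records[[cell_tag]] <- cell[cell$method %in% methods &
                                      cell$rep <= n_reps, , drop = FALSE]
        if (verbose) message("cell ", cell_tag, ": restored from checkpoint")
        next
      }
    }
    cell_cfg <- cfg
    cell_cfg$scenario <- sc
    cell_cfg$noise_sd <- ns
    t0 <- proc.time()[["elapsed"]]
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- derive_seed(base_seed, sc, format(ns), m_p, r)
      res <- run_repetition(cell_cfg, m_p, methods, rep_seed,
                            test_noise_sd = test_noise_sd)
      reps[[r]] <- cbind(data.frame(scenario = sc, noise_sd = ns,
                                    m_p = as.integer(m_p), rep = r,
                                    stringsAsFactors = FALSE), res)
    }
    cell <- do.call(rbind, reps)
    records[[cell_tag]] <- cell
    if (!is.null(cp_file))
      utils::write.csv(cell, cp_file, row.names = FALSE)
    if (verbose)
      message(sprintf("cell %s: %d reps in %.1fs", cell_tag, n_reps,
                      proc.time()[["elapsed"]] - t0))
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  records <- records[, c("scenario", "noise_sd", "method", "m_p", "rep",
                         "error", "tuning")]
  structure(list(records = records, base_seed = base_seed,
                 config = cfg),
            class = "pooling_experiment")
}

#' Percentile bootstrap confidence interval for a mean error
#'
#' Resamples the repetition errors with replacement and takes empirical
#' quantiles of the resampled means.
#'
#' @param errors Numeric vector of per-repetition errors (length >= 2).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param n_boot Number of bootstrap resamples, default 1000.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' bootstrap_ci(rbinom(100, 60, 0.2) / 60)
#' @export
bootstrap_ci <- function(errors, level = 0.95, n_boot = 1000) {
  if (length(errors) < 2L)
    stop("need at least two errors for a bootstrap interval", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n <- length(errors)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- colMeans(matrix(errors[idx], nrow = n))
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Summarize an experiment: mean errors with bootstrap CIs
#'
#' One row per (scenario, noise level, method, pool size) with the mean
#' prediction error over repetitions, a percentile-bootstrap confidence
#' interval, the repetition count, and — within each
#' (scenario, noise, method) — the degradation ratio of the mean error at
#' the largest pool size to the single-sample design.
#'
#' @param object A `"pooling_experiment"`.
#' @param level Bootstrap confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param ... Unused.
#' @return Data frame ordered by (scenario, noise_sd, method, m_p).
#' @export
summary.pooling_experiment <- function(object, level = 0.95, n_boot = 1000,
                                       ...) {
  summarize_records(object$records, level = level, n_boot = n_boot)
}

#' Summarize long-format experiment records
#'
#' Standalone form of [summary.pooling_experiment()], usable on records read
#' back from a CSV.
#'
#' @param records Data frame with columns scenario, noise_sd, method, m_p,
#'   rep, error.
#' @param level,n_boot Bootstrap settings.
#' @return See [summary.pooling_experiment()].
#' @export
summarize_records <- function(records, level = 0.95, n_boot = 1000) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no records to summarize", call. = FALSE)
  records <- records[order(records$scenario, records$noise_sd,
                           records$method, records$m_p, records$rep), ]
  key <- interaction(records$scenario, records$noise_sd, records$method,
                     records$m_p, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(records, key), function(d) {
    ci <- if (nrow(d) >= 2L) bootstrap_ci(d$error, level, n_boot)
          else c(lower = NA_real_, upper = NA_real_)
    data.frame(scenario = d$scenario[1], noise_sd = d$noise_sd[1],
               method = d$method[1], m_p = d$m_p[1],
               mean_error = mean(d$error),
               ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
               n_reps = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ## degradation: mean error at the largest pool size over the single-sample
  ## design, within each scenario x noise x method
  grp <- interaction(out$scenario, out$noise_sd, out$method, drop = TRUE)
  out$degradation <- NA_real_
  for (g in levels(grp)) {
    i <- which(grp == g)
    base <- out$mean_error[i][out$m_p[i] == 1L]
    top <- out$mean_error[i][out$m_p[i] == max(out$m_p[i])]
    if (length(base) == 1L && length(top) == 1L && max(out$m_p[i]) > 1L)
      out$degradation[i] <- top / base
  }
  out[order(out$scenario, out$noise_sd, out$method, out$m_p), ]
}

#' @export
print.pooling_experiment <- function(x, ...) {
  r <- x$records
  cat("Pooling experiment: ", length(unique(r$scenario)), " scenario(s) x ",
      length(unique(r$noise_sd)), " noise level(s) x ",
      length(unique(r$method)), " method(s) x ",
      length(unique(r$m_p)), " pool size(s), ",
      max(r$rep), " reps (", nrow(r), " records)\n", sep = "")
  invisible(x)
}

#' Bar chart of mean prediction errors with bootstrap CI whiskers
#'
#' One panel per (scenario, noise level); methods on the x-axis with one bar
#' per pool size, mirroring the usual presentation of pooled-design
#' benchmarks.
#'
#' @param x A `"pooling_experiment"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the summary table used for plotting.
#' @export
plot.pooling_experiment <- function(x, ...) {
  s <- summary(x)
  cells <- unique(s[, c("scenario", "noise_sd")])
  oldpar <- graphics::par(mfrow = c(nrow(cells), 1),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (i in seq_len(nrow(cells))) {
    d <- s[s$scenario == cells$scenario[i] & s$noise_sd == cells$noise_sd[i], ]
    methods <- unique(d$method)
    pools <- sort(unique(d$m_p))
    h <- matrix(NA_real_, length(pools), length(methods),
                dimnames = list(pools, methods))
    lo <- h; up <- h
    for (j in seq_len(nrow(d))) {
      h[as.character(d$m_p[j]), d$method[j]] <- d$mean_error[j]
      lo[as.character(d$m_p[j]), d$method[j]] <- d$ci_lower[j]
      up[as.character(d$m_p[j]), d$method[j]] <- d$ci_upper[j]
    }
    bp <- graphics::barplot(h, beside = TRUE, ylim = c(0, max(up, 0.5, na.rm = TRUE)),
                            ylab = "prediction error",
                            main = sprintf("%s, noise sd %s", cells$scenario[i],
                                           format(cells$noise_sd[i])), ...)
    graphics::arrows(bp, lo, bp, up, angle = 90, code = 3, length = 0.03)
  }
  invisible(s)
}
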