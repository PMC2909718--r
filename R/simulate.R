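#' Draw a matrix of non-informative background expression
#'
#' Background log2 expression values are i.i.d. normal with the configured
#' background mean and biological standard deviation; they carry no class
#' signal.
#'
#' @param n_samples,n_cols Matrix dimensions (rows are samples).
#' @param cfg A [sim_config()] supplying `background_mean` and `bio_sd`.
#' @return `n_samples x n_cols` numeric matrix.
#' @export
draw_background <- function(n_samples, n_cols, cfg = sim_config()) {
  if (n_samples < 1L || n_cols < 1L)
    stop("n_samples and n_cols must be positive", call. = FALSE)
  matrix(stats::rnorm(n_samples * n_cols, cfg$background_mean, cfg$bio_sd),
         nrow = n_samples, ncol = n_cols)
}

#' Simulate the block of independent differentially expressed genes
#'
#' For each of the `n_de_genes` columns a class-A mean \eqn{\mu_A} is drawn
#' uniformly from `class_mean_interval` and a shift \eqn{\Delta} uniformly
#' from `de_delta_interval`; class-A rows are \eqn{N(\mu_A, \sigma^2)} and
#' class-B rows \eqn{N(\mu_A + \Delta, \sigma^2)}. Rows are ordered class A
#' then class B.
#'
#' @param cfg A [sim_config()].
#' @param params Optional list with `mu_a` and `delta` vectors (one entry
#'   per DE gene) fixing the gene-level parameters instead of drawing fresh
#'   ones — used to generate a test set matching a training set.
#' @return A list with `x` (`2 n_per_class x n_de_genes` matrix of biological
#'   log2 values), `delta` (the realized per-column shifts) and `mu_a` (the
#'   realized class-A means).
#' @export
simulate_de_block <- function(cfg = sim_config(), params = NULL) {
  validate_sim_config(cfg)
  n <- cfg$n_per_class
  g <- cfg$n_de_genes
  x <- matrix(NA_real_, nrow = 2L * n, ncol = g)
  if (is.null(params)) {
    mu_a <- stats::runif(g, cfg$class_mean_interval[1], cfg$class_mean_interval[2])
    delta <- stats::runif(g, cfg$de_delta_interval[1], cfg$de_delta_interval[2])
  } else {
    mu_a <- params$mu_a
    delta <- params$delta
    stopifnot(length(mu_a) == g, length(delta) == g)
  }
  for (j in seq_len(g)) {
    x[seq_len(n), j] <- stats::rnorm(n, mu_a[j], cfg$bio_sd)
    x[n + seq_len(n), j] <- stats::rnorm(n, mu_a[j] + delta[j], cfg$bio_sd)
  }
  list(x = x, delta = delta, mu_a = mu_a)
}

#' Simulate the block of bivariate linear patterns
#'
#' Each pattern occupies two adjacent columns (g1, g2). The first gene g1 is
#' drawn with a per-pattern mean shared by both classes; the second gene is
#' the deterministic biological relation g2 = 2 g1 for class A and
#' g2 = 2 g1 + delta for class B (no technical noise at this stage). The
#' class offset on g2 makes the pattern linearly separable in the (g1, g2)
#' plane even though g1 alone carries no signal.
#'
#' @param cfg A [sim_config()].
#' @param params Optional list with a `mu` vector (one entry per pattern)
#'   fixing the per-pattern means instead of drawing fresh ones.
#' @return A list with `x` (`2 n_per_class x 2 n_patterns` matrix, columns
#'   ordered g1, g2 per pattern), `pairing` (data frame mapping each g2
#'   column to its g1 column) and `mu` (the realized per-pattern means).
#' @export
simulate_pattern_block <- function(cfg = sim_config(), params = NULL) {
  validate_sim_config(cfg)
  n <- cfg$n_per_class
  k <- cfg$n_patterns
  x <- matrix(NA_real_, nrow = 2L * n, ncol = 2L * k)
  b_rows <- n + seq_len(n)
  if (is.null(params)) {
    mu <- stats::runif(k, cfg$class_mean_interval[1], cfg$class_mean_interval[2])
  } else {
    mu <- params$mu
    stopifnot(length(mu) == k)
  }
  for (j in seq_len(k)) {
    g1 <- stats::rnorm(2L * n, mu[j], cfg$bio_sd)
    g2 <- 2 * g1
    g2[b_rows] <- g2[b_rows] + cfg$pattern_offset
    x[, 2L * j - 1L] <- g1
    x[, 2L * j] <- g2
  }
  pairing <- data.frame(pattern = seq_len(k),
                        g1_col = 2L * seq_len(k) - 1L,
                        g2_col = 2L * seq_len(k))
  list(x = x, pairing = pairing, mu = mu)
}

#' Add technical (measurement) noise to a log2 expression matrix
#'
#' Implements the measurement model Y = X + epsilon with epsilon i.i.d.
#' \eqn{N(0, \sigma_\epsilon^2)}, independent across all entries (one draw
#' per hybridized array and gene).
#'
#' @param x Numeric matrix of biological log2 values.
#' @param noise_sd Technical standard deviation (>= 0).
#' @return Matrix of the same shape; identical to `x` when `noise_sd = 0`.
#' @export
add_technical_noise <- function(x, noise_sd) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  if (noise_sd == 0) return(x)
  x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow = nrow(x))
}

#' Simulate a complete two-class expression dataset
#'
#' Assembles the scenario's informative block(s) and the non-informative
#' background into a samples-by-features matrix of biological values `X`,
#' adds technical noise to obtain the measured matrix `Y`, and records the
#' ground-truth role of every column. Informative columns lead the matrix
#' (DE genes first, then pattern pairs) unless `cfg$shuffle_columns`.
#'
#' Within one Monte-Carlo repetition the training and test set describe the
#' same biological situation: the realized gene-level parameters (per-DE-gene
#' \eqn{\mu_A} and \eqn{\Delta}, per-pattern mean) are stored in `$params`
#' and can be passed back in to generate a matching dataset in which only
#' the subjects and the technical noise are redrawn.
#'
#' @param cfg A [sim_config()]. If `cfg$seed` is non-`NULL` the RNG is seeded
#'   first, making the dataset a pure function of the config.
#' @param params Optional `$params` of a previous dataset, fixing the
#'   gene-level parameters (fresh draws otherwise).
#' @return An object of class `"expression_dataset"`: a list with matrices
#'   `X` and `Y` (rows `s01...`, columns `g0001...`), factor `labels`
#'   (levels A, B), data frame `truth` (feature, role, delta, pattern), the
#'   realized `params`, and the generating `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(scenario = "COMBINED", seed = 7))
#' ds
#' table(ds$truth$role)
#' test <- simulate_dataset(ds$config, params = ds$params)  # same genes
#' @export
simulate_dataset <- function(cfg = sim_config(), params = NULL) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n2 <- 2L * cfg$n_per_class
  blocks <- list()
  roles <- character(0)
  delta <- numeric(0)
  pattern <- integer(0)
  params_out <- list(de = NULL, pattern = NULL)
  if (cfg$scenario %in% c("DE_ONLY", "COMBINED") && cfg$n_de_genes > 0L) {
    de <- simulate_de_block(cfg, params = params$de)
    blocks <- c(blocks, list(de$x))
    roles <- c(roles, rep("de", cfg$n_de_genes))
    delta <- c(delta, de$delta)
    pattern <- c(pattern, rep(NA_integer_, cfg$n_de_genes))
    params_out$de <- list(mu_a = de$mu_a, delta = de$delta)
  }
  if (cfg$scenario %in% c("LINEAR_ONLY", "COMBINED") && cfg$n_patterns > 0L) {
    pat <- simulate_pattern_block(cfg, params = params$pattern)
    params_out$pattern <- list(mu = pat$mu)
    blocks <- c(blocks, list(pat$x))
    roles <- c(roles, rep(c("pattern_g1", "pattern_g2"), cfg$n_patterns))
    delta <- c(delta, rep(NA_real_, 2L * cfg$n_patterns))
    pattern <- c(pattern, rep(seq_len(cfg$n_patterns), each = 2L))
  }
  n_bg <- cfg$n_features - n_informative(cfg)
  if (n_bg > 0L) {
    blocks <- c(blocks, list(draw_background(n2, n_bg, cfg)))
    roles <- c(roles, rep("background", n_bg))
    delta <- c(delta, rep(NA_real_, n_bg))
    pattern <- c(pattern, rep(NA_integer_, n_bg))
  }
  x <- do.call(cbind, blocks)
  if (cfg$shuffle_columns) {
    ord <- sample.int(cfg$n_features)
    x <- x[, ord, drop = FALSE]
    roles <- roles[ord]
    delta <- delta[ord]
    pattern <- pattern[ord]
  }
  dimnames(x) <- list(sprintf("s%03d", seq_len(n2)),
                      sprintf("g%04d", seq_len(cfg$n_features)))
  y <- add_technical_noise(x, cfg$noise_sd)
  structure(list(
    X = x,
    Y = y,
    labels = factor(rep(c("A", "B"), each = cfg$n_per_class), levels = c("A", "B")),
    truth = data.frame(feature = colnames(x), role = roles, delta = delta,
                       pattern = pattern, stringsAsFactors = FALSE),
    params = params_out,
    config = cfg
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Two-class expression dataset (", x$config$scenario, "): ",
      nrow(x$Y), " samples x ", ncol(x$Y), " features\n", sep = "")
  tab <- table(x$truth$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  noise sd:", x$config$noise_sd, "\n")
  invisible(x)
}
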