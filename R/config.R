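#' Simulation configuration
#'
#' Collects every generative parameter of the expression simulator in one
#' validated object. The defaults reproduce the reference study conditions:
#' two classes of 30 subjects, 1000 features, a non-informative background of
#' \eqn{N(8, 0.2^2)} log2 values, ten independent differentially expressed
#' genes with per-gene shift \eqn{\Delta \sim U[0.1, 0.5]}, and/or ten
#' bivariate linear patterns with class offset \eqn{\delta = 0.4}.
#'
#' @param n_per_class Number of subjects per class (default 30).
#' @param n_features Total number of features (columns, default 1000).
#' @param n_de_genes Number of independent differentially expressed genes
#'   (used by scenarios `"DE_ONLY"` and `"COMBINED"`, default 10).
#' @param n_patterns Number of bivariate linear patterns, each occupying two
#'   columns (scenarios `"LINEAR_ONLY"` and `"COMBINED"`, default 10).
#' @param background_mean Mean of non-informative log2 expression (default 8).
#' @param bio_sd Biological standard deviation \eqn{\sigma} on the log2 scale
#'   (default 0.2).
#' @param noise_sd Technical (measurement) standard deviation
#'   \eqn{\sigma_\epsilon}; the study evaluates 0.2 and 0.4 (default 0.2).
#' @param de_delta_interval Interval for the uniform draw of the per-gene
#'   class-B shift \eqn{\Delta} (default `c(0.1, 0.5)`).
#' @param pattern_offset Class-B offset \eqn{\delta} on the second gene of a
#'   linear pattern (default 0.4).
#' @param class_mean_interval Interval for the uniform draw of per-gene (or
#'   per-pattern) baseline means \eqn{\mu_A} (default `c(6, 10)`).
#' @param scenario One of `"DE_ONLY"`, `"LINEAR_ONLY"`, `"COMBINED"`.
#' @param seed Optional integer seed; when set, [simulate_dataset()] seeds the
#'   RNG before drawing so identical configs yield bit-identical datasets.
#' @param shuffle_columns If `TRUE` the informative columns are scattered at
#'   random positions instead of leading the matrix (default `FALSE`).
#'
#' @return An object of class `"sim_config"` (a named list).
#' @examples
#' cfg <- sim_config(scenario = "COMBINED", seed = 1)
#' cfg
#' @export
sim_config <- function(n_per_class = 30,
                       n_features = 1000,
                       n_de_genes = 10,
                       n_patterns = 10,
                       background_mean = 8,
                       bio_sd = 0.2,
                       noise_sd = 0.2,
                       de_delta_interval = c(0.1, 0.5),
                       pattern_offset = 0.4,
                       class_mean_interval = c(6, 10),
                       scenario = c("DE_ONLY", "LINEAR_ONLY", "COMBINED"),
                       seed = NULL,
                       shuffle_columns = FALSE) {
  scenario <- match.arg(scenario)
  cfg <- list(n_per_class = as.integer(n_per_class),
              n_features = as.integer(n_features),
              n_de_genes = as.integer(n_de_genes),
              n_patterns = as.integer(n_patterns),
              background_mean = background_mean,
              bio_sd = bio_sd,
              noise_sd = noise_sd,
              de_delta_interval = as.numeric(de_delta_interval),
              pattern_offset = pattern_offset,
              class_mean_interval = as.numeric(class_mean_interval),
              scenario = scenario,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              shuffle_columns = isTRUE(shuffle_columns))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_per_class < 2L)
    stop("n_per_class must be at least 2", call. = FALSE)
  if (cfg$n_features < 1L)
    stop("n_features must be positive", call. = FALSE)
  if (cfg$n_de_genes < 0L || cfg$n_patterns < 0L)
    stop("n_de_genes and n_patterns must be non-negative", call. = FALSE)
  k <- n_informative(cfg)
  if (k > cfg$n_features)
    stop("informative columns (", k, ") exceed n_features (",
         cfg$n_features, ")", call. = FALSE)
  if (!(cfg$bio_sd > 0))
    stop("bio_sd must be strictly positive", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  if (length(cfg$de_delta_interval) != 2L ||
      cfg$de_delta_interval[1] > cfg$de_delta_interval[2])
    stop("de_delta_interval must be an ordered pair", call. = FALSE)
  if (cfg$de_delta_interval[1] < 0)
    stop("de_delta_interval lower bound must be >= 0", call. = FALSE)
  if (length(cfg$class_mean_interval) != 2L ||
      cfg$class_mean_interval[1] > cfg$class_mean_interval[2])
    stop("class_mean_interval must be an ordered pair", call. = FALSE)
  invisible(cfg)
}

#' Number of informative (non-background) columns implied by a config
#' @param cfg A [sim_config()].
#' @return Integer count: DE genes plus two columns per linear pattern, as
#'   applicable to the scenario.
#' @export
n_informative <- function(cfg) {
  de <- if (cfg$scenario %in% c("DE_ONLY", "COMBINED")) cfg$n_de_genes else 0L
  pat <- if (cfg$scenario %in% c("LINEAR_ONLY", "COMBINED")) 2L * cfg$n_patterns else 0L
  as.integer(de + pat)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (", x$scenario, ")\n", sep = "")
  cat("  samples : ", 2L * x$n_per_class, " (", x$n_per_class, " per class)\n",
      sep = "")
  cat("  features: ", x$n_features, " (", n_informative(x),
      " informative)\n", sep = "")
  cat("  background N(", x$background_mean, ", ", x$bio_sd, "^2), noise sd ",
      x$noise_sd, "\n", sep = "")
  if (x$scenario %in% c("DE_ONLY", "COMBINED"))
    cat("  DE genes: ", x$n_de_genes, ", delta ~ U[",
        x$de_delta_interval[1], ", ", x$de_delta_interval[2], "]\n", sep = "")
  if (x$scenario %in% c("LINEAR_ONLY", "COMBINED"))
    cat("  patterns: ", x$n_patterns, ", offset delta = ",
        x$pattern_offset, "\n", sep = "")
  invisible(x)
}

#' Derive a reproducible child seed from a base seed and labels
#'
#' Hashes the base seed together with an arbitrary sequence of labels
#' (scenario, noise level, method, pool size, repetition index, ...) into an
#' integer in `[1, 2^31 - 2]`. Used throughout the experiment engine so that
#' every repetition of every grid cell is independently reproducible from the
#' base seed alone.
#'
#' @param base_seed Integer base seed.
#' @param ... Further atomic labels mixed into the hash (coerced to character).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "DE_ONLY", 0.2, "pplsda", 5, 17)
#' @export
derive_seed <- function(base_seed, ...) {
  key <- paste(c(format(base_seed), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  bytes <- utf8ToInt(key)
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- (as.double(base_seed) %% m + 1) %% m
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1)) + 1L
}
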