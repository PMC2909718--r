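#' Randomly assign samples of each class to equally sized pools
#'
#' Partitions each class's samples into `n_per_class / m_p` pools of size
#' `m_p`, drawing members uniformly without replacement; every sample
#' contributes to exactly one pool. `m_p = 1` is the identity (single-sample)
#' design and consumes no randomness.
#'
#' @param labels Factor (or character) of per-sample class labels.
#' @param m_p Pool size; must divide the per-class sample count.
#' @return An object of class `"pool_assignment"`: list with `m_p`,
#'   `n_pools_per_class`, and `pools` (data frame: pool, class, sample).
#' @examples
#' set.seed(1)
#' assign_pools(rep(c("A", "B"), each = 30), 5)
#' @export
assign_pools <- function(labels, m_p) {
  labels <- as.factor(labels)
  m_p <- as.integer(m_p)
  if (m_p < 1L) stop("m_p must be >= 1", call. = FALSE)
  counts <- table(labels)
  if (any(counts %% m_p != 0L))
    stop("pool size ", m_p, " does not divide the class sizes (",
         paste(counts, collapse = ", "), ")", call. = FALSE)
  pools <- list()
  pool_id <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (m_p > 1L) idx <- idx[sample.int(length(idx))]
    n_pools <- length(idx) %/% m_p
    for (p in seq_len(n_pools)) {
      pool_id <- pool_id + 1L
      members <- idx[(p - 1L) * m_p + seq_len(m_p)]
      pools[[pool_id]] <- data.frame(pool = pool_id, class = cl,
                                     sample = members,
                                     stringsAsFactors = FALSE)
    }
  }
  out <- list(m_p = m_p,
              n_pools_per_class = as.integer(min(counts) %/% m_p),
              pools = do.call(rbind, pools))
  class(out) <- "pool_assignment"
  out
}

#' @export
print.pool_assignment <- function(x, ...) {
  cat("Pool assignment: m_p =", x$m_p, "->", x$n_pools_per_class,
      "pools per class\n")
  invisible(x)
}

#' Pool log2 expression values on the raw scale
#'
#' The ideal pool measures the average RNA of its members, which mixes on the
#' original (raw) scale: values are exponentiated base 2, averaged within
#' each pool, and re-logged. By Jensen's inequality the pooled value is never
#' below the arithmetic mean of the member log2 values.
#'
#' @param x Samples-by-features matrix of log2 values.
#' @param assignment A [assign_pools()] result consistent with `x`'s rows.
#' @return Pools-by-features matrix, rows ordered by pool id and named
#'   `p<id>`.
#' @examples
#' pool_expression(matrix(c(3, 5), nrow = 2),
#'                 assign_pools(c("A", "A"), 2))  # log2((8+32)/2)
#' @export
pool_expression <- function(x, assignment) {
  stopifnot(inherits(assignment, "pool_assignment"))
  pools <- assignment$pools
  if (any(pools$sample < 1L) || any(pools$sample > nrow(x)))
    stop("pool member index out of range for the given matrix", call. = FALSE)
  raw <- 2^x[pools$sample, , drop = FALSE]
  summed <- rowsum(raw, group = pools$pool, reorder = TRUE)
  out <- log2(summed / assignment$m_p)
  rownames(out) <- sprintf("p%03d", sort(unique(pools$pool)))
  colnames(out) <- colnames(x)
  out
}

#' Build a pooled training set from an expression dataset
#'
#' Pools are formed from the biological matrix `X` (pooling happens at the
#' RNA level, before measurement), then a single technical error per pool and
#' gene is added — one array per pool. With `m_p = 1` this reproduces the
#' single-sample measurement construction of the dataset itself (fresh noise
#' draw, identical distribution).
#'
#' @param ds An [simulate_dataset()] result.
#' @param m_p Pool size (must divide `n_per_class`).
#' @param noise_sd Technical sd for the pooled arrays; defaults to the
#'   dataset's configured noise level.
#' @return List with `Y` (pools x features measured matrix), `labels`
#'   (factor, one per pool), and the `assignment`.
#' @export
pooled_training_set <- function(ds, m_p, noise_sd = ds$config$noise_sd) {
  stopifnot(inherits(ds, "expression_dataset"))
  assignment <- assign_pools(ds$labels, m_p)
  pooled <- pool_expression(ds$X, assignment)
  y <- add_technical_noise(pooled, noise_sd)
  first <- !duplicated(assignment$pools$pool)
  labels <- factor(assignment$pools$class[first][order(assignment$pools$pool[first])],
                   levels = levels(ds$labels))
  list(Y = y, labels = labels, assignment = assignment)
}

#' Variance of the class mean under single-sample and pooled designs
#'
#' For n subjects measured individually the mean of a gene's measured values
#' has variance (sigma^2 + sigma_eps^2) / n; pooling the same n subjects into
#' n_P = n / m_p pools of size m_p gives (sigma^2 / m_p + sigma_eps^2) / n_P.
#' With no technical noise the two designs have equal total variance at equal
#' subject count; with noise the pooled design is strictly more precise
#' because fewer arrays contribute measurement error.
#'
#' @param sigma Biological sd.
#' @param sigma_eps Technical sd.
#' @param n Total subjects per class.
#' @param m_p Pool size (must divide `n`).
#' @return Named list `var_single`, `var_pooled`, `n_pools`.
#' @examples
#' design_variance(0.2, 0.2, 30, 1)
#' design_variance(0.2, 0.2, 30, 5)
#' @export
design_variance <- function(sigma, sigma_eps, n, m_p) {
  if (sigma < 0 || sigma_eps < 0) stop("variances must be >= 0", call. = FALSE)
  n <- as.integer(n); m_p <- as.integer(m_p)
  if (m_p < 1L || n %% m_p != 0L)
    stop("m_p must divide n", call. = FALSE)
  n_pools <- n %/% m_p
  list(var_single = (sigma^2 + sigma_eps^2) / n,
       var_pooled = (sigma^2 / m_p + sigma_eps^2) / n_pools,
       n_pools = n_pools)
}
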