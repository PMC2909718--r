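## Powered partial least squares (PPLS) component extraction and the
## discriminant classifier built on top of it (PPLS-DA).
##
## Loading weights per component follow the powered-PLS family: with
## per-feature response correlation rho_g and standard deviation s_g, and a
## trade-off parameter gamma in [0, 1],
##
##   w_g(gamma)  ∝  sign(rho_g) * (|rho_g|/max|rho|)^(gamma/(1-gamma))
##                              * (s_g/max s)^((1-gamma)/gamma)
##
## gamma = 0.5 recovers classic PLS (weights proportional to covariances);
## gamma -> 1 concentrates all weight on the best-correlated feature(s);
## gamma -> 0 on the highest-variance feature(s). Normalizing by the maxima
## keeps the powers in [0, 1] and makes the endpoints well-defined limits.

powered_weights <- function(rho, s, gamma) {
  if (gamma <= 0) {
    w <- as.numeric(s == max(s))
  } else if (gamma >= 1) {
    aro <- abs(rho)
    w <- sign(rho) * (aro == max(aro))
  } else {
    aro <- abs(rho)
    mc <- max(aro)
    ms <- max(s)
    cn <- if (mc > 0) aro / mc else rep(0, length(aro))
    sn <- if (ms > 0) s / ms else rep(0, length(s))
    w <- sign(rho) * cn^(gamma / (1 - gamma)) * sn^((1 - gamma) / gamma)
  }
  w
}

#' Extract powered partial least squares components
#'
#' Sequentially extracts latent components maximizing association with a
#' two-class response. Per component, a loading-weight vector over features
#' is built from each feature's correlation with the class-coded response
#' and its standard deviation, tempered by a power parameter; the power is
#' chosen on a fixed grid in `[lower, upper]` to maximize the squared
#' correlation between the candidate score and the response. Each component
#' is deflated from the predictor matrix before the next is extracted, so
#' successive score vectors are orthogonal.
#'
#' @param x Samples-by-features numeric matrix (need not be centered; column
#'   means are removed internally and stored).
#' @param y Two-level factor (or any vector coercible to one).
#' @param ncomp Number of components to extract (capped at `nrow(x) - 2`).
#' @param lower,upper Bounds of the power-parameter search interval, both in
#'   `[0, 1]`. `lower = upper = 0.5` fixes classic PLS weights.
#' @param n_gamma Number of grid points for the power search (default 21).
#' @return Object of class `"ppls_components"`: centering means, loading
#'   weights `W`, loadings `P`, projection matrix `R`, training `scores`,
#'   per-component chosen power `gamma`, and `ncomp` actually extracted
#'   (extraction stops early if the predictor matrix is exhausted).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 8), 40)
#' y <- factor(rep(c("A", "B"), each = 20))
#' x[y == "B", 1] <- x[y == "B", 1] + 2
#' fit <- ppls_components(x, y, ncomp = 2)
#' round(crossprod(fit$scores), 8)  # orthogonal scores
#' @export
ppls_components <- function(x, y, ncomp, lower = 0, upper = 1, n_gamma = 21) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  p <- ncol(x)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  ncomp <- min(as.integer(ncomp), n - 2L)
  if (ncomp < 1L) stop("too few samples for even one component", call. = FALSE)
  yc <- as.numeric(y == levels(y)[2])
  yc <- yc - mean(yc)
  sy <- sqrt(sum(yc^2) / (n - 1))
  means <- colMeans(x)
  xd <- sweep(x, 2, means, check.margin = FALSE)
  if (all(colSums(xd^2) == 0))
    stop("all predictors have zero variance", call. = FALSE)
  gammas <- if (lower == upper) lower else seq(lower, upper, length.out = n_gamma)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  gamma_used <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    css <- colSums(xd^2)
    s <- sqrt(css / (n - 1))
    cy <- as.numeric(crossprod(xd, yc))
    rho <- ifelse(s > 0, cy / ((n - 1) * s * sy), 0)
    cand <- vapply(gammas, powered_weights, numeric(p), rho = rho, s = s)
    tc <- xd %*% cand
    tv <- colSums(tc^2)
    cv <- as.numeric(crossprod(tc, yc))
    obj <- ifelse(tv > 0, cv^2 / tv, -Inf)  # squared correlation up to constants
    if (!any(is.finite(obj))) break
    best <- which.max(obj)
    w <- cand[, best]
    w <- w / sqrt(sum(w^2))
    t_a <- xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- as.numeric(crossprod(xd, t_a)) / tt
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    gamma_used[a] <- gammas[best]
    xd <- xd - tcrossprod(t_a, p_a)
    a_done <- a
  }
  if (a_done == 0L) stop("no informative component could be extracted", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  structure(list(means = means, W = W, P = P, R = R, scores = Tm,
                 gamma = gamma_used[seq_len(a_done)], ncomp = a_done,
                 levels = levels(y)),
            class = "ppls_components")
}

#' Project new samples onto fitted PPLS components
#' @param fit A [ppls_components()] object.
#' @param newx Matrix with the training feature count.
#' @param ncomp Number of leading components to return (default all).
#' @return Scores matrix (`nrow(newx) x ncomp`).
#' @export
ppls_project <- function(fit, newx, ncomp = fit$ncomp) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(fit$means))
    stop("feature count mismatch: model has ", length(fit$means),
         ", data has ", ncol(newx), call. = FALSE)
  sc <- sweep(newx, 2, fit$means, check.margin = FALSE) %*% fit$R
  sc[, seq_len(ncomp), drop = FALSE]
}

## Two-class Fisher linear discriminant on (low-dimensional) scores:
## direction Sw^{-1}(m2 - m1) with pooled within-class covariance and a
## midpoint threshold on the discriminant axis. Pseudo-inverse fallback when
## the pooled covariance is singular.
flda_fit <- function(scores, y) {
  scores <- as.matrix(scores)
  y <- as.factor(y)
  lev <- levels(y)
  m1 <- colMeans(scores[y == lev[1], , drop = FALSE])
  m2 <- colMeans(scores[y == lev[2], , drop = FALSE])
  n1 <- sum(y == lev[1]); n2 <- sum(y == lev[2])
  center <- function(m, mu) sweep(m, 2, mu, check.margin = FALSE)
  s1 <- crossprod(center(scores[y == lev[1], , drop = FALSE], m1))
  s2 <- crossprod(center(scores[y == lev[2], , drop = FALSE], m2))
  sw <- (s1 + s2) / max(n1 + n2 - 2L, 1L)
  dirv <- tryCatch(solve(sw, m2 - m1), error = function(e) {
    warning("singular within-class covariance; using pseudo-inverse",
            call. = FALSE)
    as.numeric(MASS::ginv(sw) %*% (m2 - m1))
  })
  list(dir = as.numeric(dirv), threshold = sum(dirv * (m1 + m2) / 2),
       levels = lev)
}

flda_predict <- function(fl, scores) {
  proj <- as.matrix(scores) %*% fl$dir
  factor(ifelse(proj > fl$threshold, fl$levels[2], fl$levels[1]),
         levels = fl$levels)
}

#' Powered partial least squares discriminant analysis
#'
#' Fits the two-class PPLS-DA classifier: PPLS latent components (see
#' [ppls_components()]) followed by a Fisher linear discriminant on the
#' component scores. The number of components is chosen by an inner
#' stratified cross-validation on the training set, minimizing the
#' cross-validated misclassification count (ties resolved toward fewer
#' components).
#'
#' @param x Training matrix (samples x features).
#' @param y Two-level factor of class labels.
#' @param ncomp_max Cap on the number of components (default 10; further
#'   capped at `nrow(x) - 2`).
#' @param lower,upper Power-parameter bounds, default `[0, 1]`.
#' @param n_gamma Power grid resolution (default 21).
#' @param cv_folds Inner CV folds (default 10, reduced to the smallest class
#'   size when classes are smaller).
#' @return Object of class `"pplsda"` with elements `ppls`, `flda`, `ncomp`,
#'   `cv_errors` (CV misclassification rate per candidate component count),
#'   `folds_used`, and `levels`. Supports [predict()] and [print()].
#' @examples
#' set.seed(42)
#' ds <- simulate_dataset(sim_config(n_features = 100, scenario = "COMBINED"))
#' fit <- pplsda(ds$Y, ds$labels, ncomp_max = 3, cv_folds = 5)
#' fit
#' mean(predict(fit, ds$Y) != ds$labels)  # training error
#' @export
pplsda <- function(x, y, ncomp_max = 10, lower = 0, upper = 1, n_gamma = 21,
                   cv_folds = 10) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  n <- nrow(x)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class", call. = FALSE)
  folds <- min(cv_folds, min(table(y)))
  fold_id <- stratified_folds(y, folds)
  a_max <- min(as.integer(ncomp_max), n - 2L)
  ## CV misclassification counts per candidate component count
  miss <- rep(0, a_max)
  avail <- rep(0L, a_max)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    a_f <- min(a_max, sum(tr) - 2L)
    if (a_f < 1L) next
    fit_f <- ppls_components(x[tr, , drop = FALSE], y[tr], a_f,
                             lower = lower, upper = upper, n_gamma = n_gamma)
    sc_te <- ppls_project(fit_f, x[!tr, , drop = FALSE])
    for (a in seq_len(fit_f$ncomp)) {
      fl <- flda_fit(fit_f$scores[, seq_len(a), drop = FALSE], y[tr])
      pred <- flda_predict(fl, sc_te[, seq_len(a), drop = FALSE])
      miss[a] <- miss[a] + sum(pred != y[!tr])
      avail[a] <- avail[a] + sum(!tr)
    }
  }
  ok <- avail > 0L
  cv_err <- ifelse(ok, miss / pmax(avail, 1L), Inf)
  ncomp <- which.min(cv_err)  # which.min takes the first (fewest) on ties
  fit <- ppls_components(x, y, ncomp, lower = lower, upper = upper,
                         n_gamma = n_gamma)
  fl <- flda_fit(fit$scores, y)
  structure(list(ppls = fit, flda = fl, ncomp = fit$ncomp,
                 cv_errors = cv_err, folds_used = folds,
                 gamma = fit$gamma, levels = levels(y)),
            class = "pplsda")
}

#' @export
predict.pplsda <- function(object, newdata, ...) {
  sc <- ppls_project(object$ppls, as.matrix(newdata), object$ncomp)
  flda_predict(object$flda, sc)
}

#' @export
print.pplsda <- function(x, ...) {
  cat("PPLS-DA: ", x$ncomp, " component(s) by ", x$folds_used,
      "-fold inner CV\n", sep = "")
  cat("  power parameter(s):", paste(signif(x$gamma, 3), collapse = ", "), "\n")
  cat("  CV error by ncomp :", paste(signif(x$cv_errors, 3), collapse = ", "), "\n")
  invisible(x)
}

## Stratified fold labels: samples of each class spread evenly over folds in
## random order.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    id[idx] <- rep_len(seq_len(k), length(idx))
  }
  id
}
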