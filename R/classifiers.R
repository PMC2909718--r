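## The five classification methods behind a single fit/predict contract.
## Each trainer returns a "trained_model": the method tag, the opaque fitted
## state, and a record of tuned hyperparameters.

METHOD_TAGS <- c("svml", "svmr", "rf", "pplsda", "tlda")

new_trained_model <- function(method, fit, tuning, levels, n_features) {
  structure(list(method = method, fit = fit, tuning = tuning,
                 levels = levels, n_features = n_features),
            class = "trained_model")
}

check_two_class <- function(x, y) {
  if (nlevels(y) != 2L || any(table(y) < 2L))
    stop("training data must contain at least two samples of each of two classes",
         call. = FALSE)
  invisible(TRUE)
}

#' Train a linear-kernel support vector machine
#'
#' Soft-margin SVM with a linear kernel and fixed cost, via
#' \pkg{e1071}. Deterministic given the data.
#'
#' @param x Training matrix (samples x features).
#' @param y Two-level factor of labels.
#' @param cost Soft-margin cost parameter (default 1, the package default).
#' @return A `"trained_model"` (method tag `"svml"`).
#' @export
train_svm_linear <- function(x, y, cost = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  check_two_class(x, y)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost)
  new_trained_model("svml", fit, list(cost = cost), levels(y), ncol(x))
}

#' Train a radial-kernel support vector machine with inner CV for gamma
#'
#' Radial-basis-kernel SVM; the kernel width `gamma` is selected from a
#' logarithmic grid around the 1/n_features heuristic using \pkg{e1071}'s
#' built-in k-fold cross-validation, minimizing the CV misclassification
#' rate (ties toward the smaller gamma). Cost is fixed.
#'
#' @inheritParams train_svm_linear
#' @param gamma_grid Candidate gamma values; default `2^(-10:2) / ncol(x)`.
#' @param cv_folds Inner CV folds (default 10, reduced to the sample count
#'   when necessary).
#' @return A `"trained_model"` (method tag `"svmr"`) whose tuning record
#'   stores the grid, the CV error per candidate, and the winner.
#' @export
train_svm_radial <- function(x, y, cost = 1, gamma_grid = NULL, cv_folds = 10) {
  x <- as.matrix(x); y <- as.factor(y)
  check_two_class(x, y)
  if (is.null(gamma_grid)) gamma_grid <- 2^(-10:2) / ncol(x)
  folds <- min(cv_folds, nrow(x))
  cv_err <- vapply(gamma_grid, function(g) {
    m <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = g,
                    cross = folds)
    1 - m$tot.accuracy / 100
  }, numeric(1))
  best <- which.min(cv_err)  # first minimum = smallest gamma on ties
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost,
                    gamma = gamma_grid[best])
  new_trained_model("svmr", fit,
                    list(cost = cost, gamma_grid = gamma_grid,
                         cv_errors = cv_err, gamma = gamma_grid[best]),
                    levels(y), ncol(x))
}

#' Train a random forest classifier
#'
#' Ensemble of classification trees with majority vote, via
#' \pkg{randomForest}: 1000 trees and 20 candidate variables per split by
#' default.
#'
#' @inheritParams train_svm_linear
#' @param ntree Number of trees (default 1000).
#' @param mtry Candidate variables per split (default 20, capped at the
#'   feature count).
#' @return A `"trained_model"` (method tag `"rf"`).
#' @export
train_random_forest <- function(x, y, ntree = 1000, mtry = 20) {
  x <- as.matrix(x); y <- as.factor(y)
  check_two_class(x, y)
  mtry <- min(mtry, ncol(x))
  fit <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry)
  new_trained_model("rf", fit, list(ntree = ntree, mtry = mtry),
                    levels(y), ncol(x))
}

#' Train PPLS-DA as a trained_model
#'
#' Thin wrapper putting [pplsda()] behind the common fit/predict contract.
#'
#' @inheritParams train_svm_linear
#' @param ... Passed to [pplsda()] (`ncomp_max`, `lower`, `upper`,
#'   `n_gamma`, `cv_folds`).
#' @return A `"trained_model"` (method tag `"pplsda"`) recording the chosen
#'   component count and power parameters.
#' @export
train_pplsda <- function(x, y, ...) {
  x <- as.matrix(x); y <- as.factor(y)
  check_two_class(x, y)
  fit <- pplsda(x, y, ...)
  new_trained_model("pplsda", fit,
                    list(ncomp = fit$ncomp, gamma = fit$gamma,
                         cv_errors = fit$cv_errors),
                    levels(y), ncol(x))
}

## Vectorized two-sample column t statistics (pooled or Welch variance).
## Returns the two-sided p-value per column.
col_ttest_p <- function(x, y, var_equal = TRUE) {
  y <- as.factor(y)
  lev <- levels(y)
  x1 <- x[y == lev[1], , drop = FALSE]
  x2 <- x[y == lev[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1, check.margin = FALSE)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2, check.margin = FALSE)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

## Two-class LDA with equal priors on a small feature subset; pooled
## covariance with pseudo-inverse fallback (e.g. 12 pooled training samples
## on 10 features can be near-singular).
lda2_fit <- function(x, y) {
  y <- as.factor(y)
  lev <- levels(y)
  m1 <- colMeans(x[y == lev[1], , drop = FALSE])
  m2 <- colMeans(x[y == lev[2], , drop = FALSE])
  n1 <- sum(y == lev[1]); n2 <- sum(y == lev[2])
  c1 <- sweep(x[y == lev[1], , drop = FALSE], 2, m1, check.margin = FALSE)
  c2 <- sweep(x[y == lev[2], , drop = FALSE], 2, m2, check.margin = FALSE)
  sw <- (crossprod(c1) + crossprod(c2)) / max(n1 + n2 - 2L, 1L)
  dirv <- tryCatch(solve(sw, m2 - m1), error = function(e) {
    warning("singular pooled covariance in LDA; using pseudo-inverse",
            call. = FALSE)
    as.numeric(MASS::ginv(sw) %*% (m2 - m1))
  })
  list(dir = as.numeric(dirv), threshold = sum(dirv * (m1 + m2) / 2),
       levels = lev)
}

#' Train the t-test + LDA classifier
#'
#' Univariate two-sample t-tests rank all features by p-value; the ten best
#' candidates (ties broken by column index) feed a linear discriminant
#' analysis with pooled covariance and equal priors.
#'
#' @inheritParams train_svm_linear
#' @param n_select Number of features to keep (default 10).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return A `"trained_model"` (method tag `"tlda"`) recording the selected
#'   feature indices and their p-values.
#' @export
train_ttest_lda <- function(x, y, n_select = 10, var_equal = TRUE) {
  x <- as.matrix(x); y <- as.factor(y)
  check_two_class(x, y)
  if (ncol(x) < n_select)
    stop("need at least ", n_select, " features", call. = FALSE)
  p <- col_ttest_p(x, y, var_equal = var_equal)
  sel <- order(p)[seq_len(n_select)]  # order() breaks ties by column index
  fit <- lda2_fit(x[, sel, drop = FALSE], y)
  new_trained_model("tlda", list(lda = fit, selected = sel),
                    list(selected = sel, p_values = p[sel],
                         var_equal = var_equal),
                    levels(y), ncol(x))
}

#' Train any of the five classification methods
#'
#' Dispatcher used by the experiment engine; `method` is one of `"svml"`,
#' `"svmr"`, `"rf"`, `"pplsda"`, `"tlda"`.
#'
#' @param method Method tag.
#' @inheritParams train_svm_linear
#' @param ... Passed to the specific trainer.
#' @return A `"trained_model"`.
#' @export
train_classifier <- function(method = METHOD_TAGS, x, y, ...) {
  method <- match.arg(method)
  switch(method,
         svml = train_svm_linear(x, y, ...),
         svmr = train_svm_radial(x, y, ...),
         rf = train_random_forest(x, y, ...),
         pplsda = train_pplsda(x, y, ...),
         tlda = train_ttest_lda(x, y, ...))
}

#' Predict class labels from a trained model
#'
#' @param object A `"trained_model"`.
#' @param newdata Matrix with the training feature count (possibly zero
#'   rows).
#' @param ... Unused.
#' @return Factor of predicted labels, one per row of `newdata`.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch: model has ", object$n_features,
         ", data has ", ncol(newdata), call. = FALSE)
  if (nrow(newdata) == 0L)
    return(factor(character(0), levels = object$levels))
  out <- switch(object$method,
    svml = ,
    svmr = predict(object$fit, newdata),
    rf = predict(object$fit, newdata),
    pplsda = predict(object$fit, newdata),
    tlda = flda_predict(object$fit$lda,
                        newdata[, object$fit$selected, drop = FALSE]))
  factor(as.character(out), levels = object$levels)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("Trained classifier [", x$method, "], ", x$n_features, " features\n",
      sep = "")
  tune <- x$tuning
  if (x$method == "svmr")
    cat("  tuned gamma:", format(tune$gamma), "\n")
  if (x$method == "pplsda")
    cat("  ncomp:", tune$ncomp, " power:",
        paste(signif(tune$gamma, 3), collapse = ", "), "\n")
  if (x$method == "tlda")
    cat("  selected features:", paste(tune$selected, collapse = ", "), "\n")
  invisible(x)
}
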