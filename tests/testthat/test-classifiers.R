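test_that("all five methods separate well-separated clouds at training", {
  toy <- separable_toy()
  for (m in c("svml", "svmr", "rf", "pplsda", "tlda")) {
    set.seed(1)
    args <- list(m, cbind(toy$x, matrix(rnorm(nrow(toy$x) * 10), nrow(toy$x))),
                 toy$y)
    if (m == "pplsda") args <- c(args, list(cv_folds = 5))
    fit <- suppressWarnings(do.call(train_classifier, args))
    expect_s3_class(fit, "trained_model")
    expect_equal(mean(predict(fit, args[[2]]) != toy$y), 0, info = m)
  }
})

test_that("label-flip symmetry: swapped training labels flip predictions", {
  ds <- simulate_dataset(tiny_cfg(seed = 2))
  y_flip <- factor(ifelse(ds$labels == "A", "B", "A"), levels = c("A", "B"))
  test <- simulate_dataset(ds$config, params = ds$params)
  for (m in c("svml", "svmr", "rf", "pplsda", "tlda")) {
    args <- if (m == "pplsda") list(cv_folds = 5) else list()
    set.seed(3)
    f1 <- suppressWarnings(do.call(train_classifier,
                                   c(list(m, ds$Y, ds$labels), args)))
    set.seed(3)
    f2 <- suppressWarnings(do.call(train_classifier,
                                   c(list(m, ds$Y, y_flip), args)))
    p1 <- as.character(predict(f1, test$Y))
    p2 <- as.character(predict(f2, test$Y))
    agree <- mean(p1 == ifelse(p2 == "A", "B", "A"))
    if (m %in% c("svml", "tlda")) {
      expect_equal(agree, 1, info = m)
    } else {
      # RF growth and the inner-CV fold draws are not label-symmetric
      expect_gte(agree, 0.9)
    }
  }
  # with the component count fixed (no CV fold randomness) the PPLS-DA
  # decision rule flips exactly
  f1 <- ppls_components(ds$Y, ds$labels, 2)
  f2 <- ppls_components(ds$Y, y_flip, 2)
  d1 <- poolsim:::flda_predict(poolsim:::flda_fit(f1$scores, ds$labels),
                               ppls_project(f1, test$Y))
  d2 <- poolsim:::flda_predict(poolsim:::flda_fit(f2$scores, y_flip),
                               ppls_project(f2, test$Y))
  expect_equal(as.character(d1),
               ifelse(as.character(d2) == "A", "B", "A"))
})

test_that("radial kernel beats linear on an XOR layout at training", {
  toy <- xor_toy()
  set.seed(4)
  lin <- train_svm_linear(toy$x, toy$y)
  rad <- train_svm_radial(toy$x, toy$y, gamma_grid = 2^(-4:4), cv_folds = 5)
  err_lin <- mean(predict(lin, toy$x) != toy$y)
  err_rad <- mean(predict(rad, toy$x) != toy$y)
  expect_lt(err_rad, err_lin)
})

test_that("constant appended features do not change radial-SVM predictions", {
  toy <- separable_toy()
  set.seed(5)
  f1 <- train_svm_radial(toy$x, toy$y, gamma_grid = 0.1, cv_folds = 5)
  set.seed(5)
  f2 <- suppressWarnings(
    train_svm_radial(cbind(toy$x, 3), toy$y, gamma_grid = 0.1, cv_folds = 5))
  p1 <- predict(f1, toy$x)
  p2 <- suppressWarnings(predict(f2, cbind(toy$x, 3)))
  expect_equal(as.character(p1), as.character(p2))
})

test_that("random forest honors its tuning parameters", {
  toy <- separable_toy(n = 10)
  set.seed(6)
  fit <- train_random_forest(toy$x, toy$y, ntree = 1000)
  expect_equal(fit$tuning$ntree, 1000)
  expect_equal(fit$tuning$mtry, 2)  # capped at the feature count
  # consistent duplicate rows are learned exactly
  xdup <- rbind(toy$x, toy$x)
  ydup <- factor(rep(as.character(toy$y), 2), levels = c("A", "B"))
  set.seed(6)
  fdup <- train_random_forest(xdup, ydup, ntree = 200)
  expect_equal(mean(predict(fdup, xdup) != ydup), 0)
})

test_that("column t statistics agree with stats::t.test", {
  set.seed(7)
  x <- matrix(rnorm(40 * 6), 40)
  y <- factor(rep(c("A", "B"), each = 20))
  p_fast <- poolsim:::col_ttest_p(x, y)
  p_ref <- apply(x, 2, function(v) t.test(v ~ y, var.equal = TRUE)$p.value)
  expect_equal(unname(p_fast), unname(p_ref), tolerance = 1e-12)
  p_welch <- poolsim:::col_ttest_p(x, y, var_equal = FALSE)
  p_wref <- apply(x, 2, function(v) t.test(v ~ y)$p.value)
  expect_equal(unname(p_welch), unname(p_wref), tolerance = 1e-12)
})

test_that("t-test selection ranks a dominant feature first and is vacuous at p = 10", {
  set.seed(8)
  x <- matrix(rnorm(40 * 10), 40)
  y <- factor(rep(c("A", "B"), each = 20))
  x[y == "B", 4] <- x[y == "B", 4] + 5    # dominant
  x[y == "B", 9] <- x[y == "B", 9] + 1    # weak
  fit <- train_ttest_lda(x, y)
  expect_equal(sort(fit$tuning$selected), 1:10)   # all 10 of 10 selected
  expect_equal(fit$tuning$selected[1], 4L)        # dominant feature ranks first
  expect_error(train_ttest_lda(x[, 1:5], y), "at least 10")
})

test_that("tlda predictions ignore background columns once selection agrees", {
  ds <- simulate_dataset(tiny_cfg(seed = 9, n_de_genes = 10,
                                  scenario = "DE_ONLY",
                                  de_delta_interval = c(1, 1.5)))
  fit <- train_ttest_lda(ds$Y, ds$labels)
  expect_equal(sort(fit$tuning$selected), 1:10)  # strong signal: true features
  test <- simulate_dataset(ds$config, params = ds$params)
  p1 <- predict(fit, test$Y)
  scrambled <- test$Y
  scrambled[, 11:60] <- scrambled[sample(nrow(scrambled)), 11:60]
  expect_equal(as.character(predict(fit, scrambled)), as.character(p1))
})

test_that("prediction contract: shapes, permutation, empty input", {
  toy <- separable_toy()
  set.seed(10)
  fit <- train_svm_linear(toy$x, toy$y)
  expect_error(predict(fit, toy$x[, 1, drop = FALSE]), "mismatch")
  perm <- sample(nrow(toy$x))
  expect_equal(as.character(predict(fit, toy$x[perm, ])),
               as.character(predict(fit, toy$x))[perm])
  empty <- predict(fit, toy$x[0, , drop = FALSE])
  expect_length(empty, 0)
  expect_equal(levels(empty), c("A", "B"))
  expect_error(train_svm_linear(toy$x[1:20, ], droplevels(toy$y[1:20])),
               "two classes")
})

test_that("row permutation of the training set leaves decisions unchanged", {
  ds <- simulate_dataset(tiny_cfg(seed = 11))
  test <- simulate_dataset(ds$config, params = ds$params)
  perm <- sample(nrow(ds$Y))
  for (m in c("svml", "tlda")) {
    f1 <- train_classifier(m, ds$Y, ds$labels)
    f2 <- train_classifier(m, ds$Y[perm, ], ds$labels[perm])
    expect_equal(as.character(predict(f1, test$Y)),
                 as.character(predict(f2, test$Y)), info = m)
  }
})
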