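blob <- function(n, center, sd = 0.5, seed) {
  withr::with_seed(seed, sweep(matrix(rnorm(n * 2, sd = sd), n), 2, center, "+"))
}

test_that("the binary surrogate separates a separable toy problem", {
  X <- rbind(blob(80, c(0, 0), seed = 1), blob(80, c(6, 6), seed = 2))
  y <- rep(c(0, 1), each = 80)
  m <- train_binary_surrogate(X, y, seed = 3)
  expect_gte(m$cv_accuracy, 0.99)
  expect_identical(m$task, "binary-acceptance")
  ## determinism
  m2 <- train_binary_surrogate(X, y, seed = 3)
  expect_identical(m$cv_accuracy, m2$cv_accuracy)
  expect_error(train_binary_surrogate(X, rep(1, 160)), "single class")
})

test_that("uninformative features give chance-level accuracy", {
  withr::with_seed(8, {
    X <- matrix(rnorm(300 * 4), 300)
    y <- rbinom(300, 1, 0.7)
  })
  m <- train_binary_surrogate(X, y, seed = 9)
  base <- max(mean(y), 1 - mean(y))
  expect_lt(abs(m$cv_accuracy - base), 0.08)
})

test_that("the phenotype surrogate handles three classes one-vs-one", {
  X <- rbind(blob(60, c(0, 0), seed = 4), blob(60, c(7, 0), seed = 5),
             blob(60, c(0, 7), seed = 6))
  y <- rep(c("N", "A", "E"), each = 60)
  m <- train_phenotype_surrogate(X, y, seed = 7)
  expect_gte(m$cv_accuracy, 0.99)
  expect_identical(m$kernel, "linear")
  ## permuted labels give roughly the majority-class baseline
  yp <- withr::with_seed(10, sample(y))
  mp <- train_phenotype_surrogate(X, yp, seed = 11)
  expect_lt(mp$cv_accuracy, 0.45)
  ## stratified folds preserve class counts
  folds <- aortacohort:::stratified_folds(factor(y), 5, seed = 12)
  for (f in 1:5) {
    tb <- table(y[folds == f])
    expect_true(all(tb == 12))
  }
})

test_that("confusion matrices count correctly", {
  X <- rbind(blob(40, c(0, 0), seed = 13), blob(40, c(6, 6), seed = 14))
  y <- rep(c(0, 1), each = 40)
  m <- train_binary_surrogate(X, y, seed = 15)
  cm <- evaluate_confusion(m, X, factor(y, levels = c(0, 1)))
  expect_identical(sum(cm), 80L)
  expect_equal(sum(diag(cm)), 80)  # separable: diagonal
  ## hand-counted oracle on a 10-row set with a known predictor
  Xs <- blob(10, c(3, 3), sd = 3, seed = 16)
  ys <- factor(as.integer(Xs[, 1] > 3), levels = c(0, 1))
  pred <- predict(m, Xs)
  cm2 <- evaluate_confusion(m, Xs, ys)
  manual <- table(true = ys, predicted = pred)
  expect_equal(as.numeric(cm2), as.numeric(manual))
})

test_that("two-stage efficiency is TP / (TP + FP) with its complements", {
  cm <- as.table(rbind("0" = c("0" = 500, "1" = 116),
                       "1" = c("0" = 170, "1" = 884)))
  names(dimnames(cm)) <- c("true", "predicted")
  ts <- two_stage_efficiency(cm, "1")
  expect_equal(ts$efficiency, 884 / (884 + 116))
  expect_equal(ts$efficiency, 0.884)
  expect_equal(ts$discard_fraction, 0.116)
  expect_equal(ts$fn_rate, 170 / (170 + 884))
  ## no false positives: perfect efficiency
  cm0 <- as.table(rbind("0" = c("0" = 10, "1" = 0),
                        "1" = c("0" = 2, "1" = 30)))
  names(dimnames(cm0)) <- c("true", "predicted")
  expect_equal(two_stage_efficiency(cm0, "1")$efficiency, 1.0)
  expect_error(two_stage_efficiency(cm0, "2"), "absent")
})

test_that("two-stage efficiency equals a brute-force pipeline simulation", {
  ## labeled cohort + trained surrogate; simulate filter-then-criterion
  X <- rbind(blob(150, c(0, 0), sd = 2, seed = 17),
             blob(150, c(4, 4), sd = 2, seed = 18))
  y <- as.integer(X[, 1] + X[, 2] > 4)  # the "true criterion"
  m <- train_binary_surrogate(X, y, seed = 19)
  Xt <- blob(400, c(2, 2), sd = 3, seed = 20)
  yt <- as.integer(Xt[, 1] + Xt[, 2] > 4)
  cm <- evaluate_confusion(m, Xt, factor(yt, levels = c(0, 1)))
  ts <- two_stage_efficiency(cm, "1")
  pred <- as.integer(as.character(predict(m, Xt)))
  passed <- which(pred == 1L)
  expect_identical(length(passed), as.integer(ts$tp + ts$fp))
  expect_equal(sum(yt[passed] == 1L) / length(passed), ts$efficiency)
  ## after the authoritative criterion, no false positives remain
  final <- passed[yt[passed] == 1L]
  expect_true(all(yt[final] == 1L))
})

test_that("feature importance concentrates on informative features", {
  withr::with_seed(21, {
    X <- matrix(rnorm(400 * 5), 400)
    y <- factor(as.integer(X[, 2] > 0))
  })
  imp <- feature_importance(X, y, seed = 22)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-8)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$feature[1], "a2")
  expect_gt(imp$importance[1], 0.6)
  imp2 <- feature_importance(X, y, seed = 22)
  expect_identical(imp, imp2)
})

test_that("accuracy over top-n features plateaus once informative ones enter", {
  withr::with_seed(23, {
    X <- matrix(rnorm(300 * 6), 300)
    y <- factor(as.integer(X[, 1] + X[, 5] > 0))
  })
  curve <- accuracy_vs_topn(X, y, order = c(1, 5, 2, 3, 4, 6), n_min = 1,
                            seed = 24)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  ## with both informative features the curve is already near its maximum
  expect_gt(curve$accuracy[curve$n == 2], max(curve$accuracy) - 0.05)
  ## full-feature point equals a direct full-feature CV fit
  full <- aortacohort:::svm_cv_accuracy(X, y, 5, "linear", 24)
  expect_equal(curve$accuracy[curve$n == 6], full)
})
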