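## Machine-learning surrogates of the acceptance functions: a binary
## support-vector classifier predicting data-driven acceptance and a
## three-class (one-vs-one) SVM predicting the aortic-root phenotype, plus
## confusion accounting, two-stage screening efficiency and random-forest
## feature importance.

stratified_folds <- function(labels, folds, seed = NULL) {
  with_seed(seed, {
    idx <- integer(length(labels))
    for (lv in unique(labels)) {
      ii <- which(labels == lv)
      idx[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
    idx
  })
}

svm_cv_accuracy <- function(X, y, folds, kernel, seed) {
  fold <- stratified_folds(y, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stopf("a CV fold lost a class")
    m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                    scale = TRUE)
    pred <- stats::predict(m, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Train an SVM surrogate of a binary acceptance function
#'
#' Radial-basis-kernel support-vector classifier with stratified k-fold
#' cross-validated accuracy; the returned model is refit on all data.
#'
#' @param features matrix of feature vectors (rows).
#' @param labels 0/1 vector (or logical) of acceptance outcomes.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (controls fold assignment).
#' @param kernel SVM kernel (default `"radial"`).
#' @return A `surrogate_model` with `task = "binary-acceptance"`,
#'   `cv_accuracy` and the fitted SVM.
#' @export
train_binary_surrogate <- function(features, labels, folds = 5L, seed = NULL,
                                   kernel = "radial") {
  X <- as.matrix(features)
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) stopf("labels contain a single class")
  acc <- svm_cv_accuracy(X, y, folds, kernel, seed)
  fit <- e1071::svm(X, y, kernel = kernel, scale = TRUE)
  structure(list(task = "binary-acceptance", kernel = kernel, fit = fit,
                 cv_accuracy = acc, folds = folds, seed = seed,
                 n_train = nrow(X)),
            class = "surrogate_model")
}

#' Train an SVM surrogate of the phenotype rule
#'
#' Linear-kernel three-class support-vector classifier (one-vs-one
#' decomposition) with stratified k-fold cross-validated accuracy.
#'
#' @param features matrix of feature vectors (rows).
#' @param labels factor (or character) with levels N, A, E.
#' @inheritParams train_binary_surrogate
#' @return A `surrogate_model` with `task = "phenotype"`.
#' @export
train_phenotype_surrogate <- function(features, labels, folds = 5L,
                                      seed = NULL, kernel = "linear") {
  X <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("N", "A", "E"))
  y <- droplevels(y)
  if (nlevels(y) < 2L) stopf("labels contain a single class")
  acc <- svm_cv_accuracy(X, y, folds, kernel, seed)
  fit <- e1071::svm(X, y, kernel = kernel, scale = TRUE)
  structure(list(task = "phenotype", kernel = kernel, fit = fit,
                 cv_accuracy = acc, folds = folds, seed = seed,
                 n_train = nrow(X)),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("surrogate_model: %s (%s kernel), %d training rows, %d-fold CV accuracy %.3f\n",
              x$task, x$kernel, x$n_train, x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  stats::predict(object$fit, as.matrix(newdata))
}

#' Confusion matrix of a surrogate on held-out data
#'
#' @param model a `surrogate_model`.
#' @param features held-out feature vectors (rows).
#' @param labels true labels.
#' @return A `table` of counts, rows = true, columns = predicted.
#' @export
evaluate_confusion <- function(model, features, labels) {
  pred <- predict(model, features)
  truth <- factor(as.character(labels), levels = levels(pred))
  table(true = truth, predicted = pred)
}

#' Two-stage screening efficiency from a confusion matrix
#'
#' In two-stage screening the surrogate prefilters candidates and only
#' surrogate-accepted ones reach the authoritative acceptance function, so
#' the efficiency of the expensive stage is `TP / (TP + FP)`: among
#' candidates passed on, the fraction truly accepted. The complementary
#' discard fraction and the false-negative rate (truly acceptable anatomies
#' never evaluated) are reported alongside.
#'
#' @param cm confusion matrix from [evaluate_confusion()] (rows = true).
#' @param positive_label the accepted / target label (default `"1"`).
#' @return List with `efficiency`, `discard_fraction`, `fn_rate`, `tp`,
#'   `fp`, `fn`.
#' @export
two_stage_efficiency <- function(cm, positive_label = "1") {
  positive_label <- as.character(positive_label)
  if (!positive_label %in% colnames(cm))
    stopf("label '%s' absent from confusion matrix", positive_label)
  tp <- cm[positive_label, positive_label]
  fp <- sum(cm[, positive_label]) - tp
  fn <- sum(cm[positive_label, ]) - tp
  if (tp + fp == 0) stopf("surrogate accepted nothing; efficiency undefined")
  list(efficiency = tp / (tp + fp), discard_fraction = fp / (tp + fp),
       fn_rate = fn / max(1, sum(cm[positive_label, ])),
       tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Random-forest feature importance
#'
#' Mean decrease in node impurity per feature, normalized to sum to one,
#' with the features ranked.
#'
#' @param features matrix of feature vectors (rows).
#' @param labels class labels.
#' @param seed integer seed.
#' @param ntree number of trees (default 500).
#' @return Data frame with `feature`, `importance` (sums to 1), sorted
#'   decreasing.
#' @export
feature_importance <- function(features, labels, seed = NULL, ntree = 500L) {
  X <- as.matrix(features)
  colnames(X) <- colnames(X) %||% paste0("a", seq_len(ncol(X)))
  y <- factor(labels)
  rf <- with_seed(seed, randomForest::randomForest(X, y, ntree = ntree))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out[order(-out$importance), ]
}

#' Cross-validated accuracy over importance-ranked feature subsets
#'
#' Retrains the surrogate on the first `n = n_min..p` features in a given
#' importance order and reports the CV accuracy curve.
#'
#' @param features matrix of feature vectors.
#' @param labels class labels.
#' @param order integer vector ranking the features (most important first);
#'   default: random-forest importance order.
#' @param n_min smallest subset size (default 3).
#' @param folds,seed CV controls.
#' @param kernel SVM kernel (default `"linear"`).
#' @return Data frame with `n` and `accuracy`.
#' @export
accuracy_vs_topn <- function(features, labels, order = NULL, n_min = 3L,
                             folds = 5L, seed = NULL, kernel = "linear") {
  X <- as.matrix(features)
  p <- ncol(X)
  order <- order %||% {
    imp <- feature_importance(X, labels, seed = seed)
    match(imp$feature, colnames(X) %||% paste0("a", seq_len(p)))
  }
  y <- factor(as.character(labels))
  ns <- seq(min(n_min, p), p)
  acc <- vapply(ns, function(n) {
    svm_cv_accuracy(X[, order[seq_len(n)], drop = FALSE], y, folds, kernel,
                    seed)
  }, numeric(1))
  data.frame(n = ns, accuracy = acc)
}
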