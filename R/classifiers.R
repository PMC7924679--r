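# Thin wrappers over established classifier implementations. The package's
# contribution is the features and the binding algorithm; classification is
# delegated, with parameters fixed to the harness defaults: polynomial-kernel
# SVM with cost 1, 100-tree random forest, linear-search KNN without distance
# weighting, Gaussian naive Bayes, and SAMME-boosted decision trees.

fit_predict_classifier <- function(classifier, x_train, y_train, x_test, ...) {
  y_train <- factor(y_train)
  switch(classifier,
    svm = {
      # polynomial kernel, cost 1; exponent 1 is the Weka SMO PolyKernel
      # default this harness mirrors
      fit <- e1071::svm(x_train, y_train, kernel = "polynomial", cost = 1,
                        degree = 1, coef0 = 0, scale = FALSE, ...)
      as.character(predict(fit, x_test))
    },
    rf = {
      fit <- randomForest::randomForest(x_train, y_train, ntree = 100, ...)
      as.character(predict(fit, x_test))
    },
    knn = {
      as.character(class::knn(x_train, x_test, y_train, ...))
    },
    nb = {
      fit <- e1071::naiveBayes(x_train, y_train, ...)
      as.character(predict(fit, x_test))
    },
    adaboost = {
      fit <- adaboost_fit(x_train, y_train, ...)
      adaboost_predict(fit, x_test)
    },
    stop("unknown classifier spec '", classifier, "'", call. = FALSE)
  )
}

#' Fit a SAMME AdaBoost ensemble of decision trees
#'
#' Multi-class AdaBoost (SAMME) with `rpart` decision trees as the weak base
#' learner: each round fits a depth-limited tree to the weighted training
#' set, weights of misclassified instances are increased, and rounds vote
#' with weight `log((1 - err) / err) + log(K - 1)`.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels.
#' @param n_rounds Number of boosting rounds.
#' @param maxdepth Maximum depth of each base tree.
#' @return An object of class `adaboost` (list of trees and their weights).
#' @export
adaboost_fit <- function(x, y, n_rounds = 50L, maxdepth = 5L) {
  y <- factor(y)
  k <- nlevels(y)
  n <- length(y)
  stopifnot(k >= 2, nrow(x) == n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, xval = 0,
                                                       minsplit = 2))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / k) break           # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-10) break                # perfect fit; further rounds add nothing
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y)),
            class = "adaboost")
}

#' Predict classes from a SAMME AdaBoost ensemble
#'
#' @param fit An [adaboost_fit()] object.
#' @param x Numeric feature matrix of test instances.
#' @return Character vector of predicted class labels.
#' @export
adaboost_predict <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  scores <- matrix(0, nrow(df), length(fit$levels),
                   dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$trees)) {
    pred <- as.character(predict(fit$trees[[m]], df, type = "class"))
    scores[cbind(seq_len(nrow(df)), match(pred, fit$levels))] <-
      scores[cbind(seq_len(nrow(df)), match(pred, fit$levels))] +
      fit$alphas[m]
  }
  fit$levels[max.col(scores, ties.method = "first")]
}
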