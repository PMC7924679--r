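#' Stratified cross-validation folds
#'
#' Partitions indices into `n_folds` folds so that per-class counts across
#' folds differ by at most one.
#'
#' @param labels Class labels, one per instance.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return A list of `n_folds` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  bad <- names(counts)[counts < n_folds]
  if (length(bad)) {
    stop("class(es) with fewer members than folds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  folds <- vector("list", n_folds)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(n_folds), length(idx))
      for (f in seq_len(n_folds)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Confusion matrix with fixed class levels
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param levels Class levels ordering the rows/columns; defaults to the
#'   union of observed labels.
#' @return A k x k integer matrix, true classes in rows, predictions in
#'   columns.
#' @export
confusion_matrix <- function(truth, predicted,
                             levels = sort(unique(c(as.character(truth),
                                                    as.character(predicted))))) {
  t1 <- factor(as.character(truth), levels = levels)
  t2 <- factor(as.character(predicted), levels = levels)
  unclass(table(truth = t1, predicted = t2))
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy is the diagonal share. Sensitivity, specificity and F1 are
#' computed one-vs-rest per class and aggregated by class-support-weighted
#' averaging, which for a binary matrix reduces to the usual definitions
#' when the positive class is the first level. All metrics are reported as
#' percentages.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return A list of class `metric_report` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `f1` and `per_class` (a data frame).
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  stopifnot(total > 0, nrow(cm) == ncol(cm))
  k <- nrow(cm)
  per <- data.frame(class = rownames(cm), support = rowSums(cm),
                    sensitivity = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, row.names = NULL)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (is.na(sens) || prec + sens == 0) 0 else
      2 * prec * sens / (prec + sens)
    per$sensitivity[i] <- 100 * sens
    per$specificity[i] <- 100 * spec
    per$f1[i] <- 100 * f1
  }
  w <- per$support / total
  structure(list(
    accuracy = 100 * sum(diag(cm)) / total,
    sensitivity = sum(w * per$sensitivity),
    specificity = sum(w * per$specificity),
    f1 = sum(w * per$f1),
    per_class = per
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  f1 %.2f%%\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

# Min-max normalise columns by training ranges (constant columns map to 0).
.fit_normalizer <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
.apply_normalizer <- function(x, nz) {
  sweep(sweep(x, 2, nz$lo), 2, nz$rng, "/")
}

#' Run a stratified cross-validated classification experiment
#'
#' For each fold the remaining folds form the training partition, which is
#' SMOTE-balanced ([balance_training_set()]) before fitting; the held-out
#' fold is evaluated untouched, so no synthetic instance can appear in any
#' test set (the returned audit verifies this structurally). Features are
#' min-max normalised using training-fold ranges.
#'
#' Supported classifier specs and their parameters:
#' `"svm"` (polynomial kernel, cost 1), `"rf"` (100 trees), `"knn"`
#' (linear-search k-nearest-neighbour, k = 1), `"nb"` (Gaussian naive
#' Bayes) and `"adaboost"` (SAMME boosting of decision trees).
#'
#' @param x Numeric feature matrix.
#' @param labels Class labels, one per row.
#' @param classifier One of `"svm"`, `"rf"`, `"knn"`, `"nb"`, `"adaboost"`.
#' @param n_folds Number of stratified folds.
#' @param seed Integer seed (folds, SMOTE and stochastic classifiers).
#' @param smote Balance training folds with SMOTE?
#' @param ... Extra arguments passed to the classifier wrapper (e.g. `k`
#'   for knn, `n_rounds` for adaboost).
#' @return An object of class `class_experiment`: per-fold metric reports,
#'   their mean, fold assignments and the SMOTE audit.
#' @export
run_class_experiment <- function(x, labels, classifier = c("svm", "rf", "knn",
                                                           "nb", "adaboost"),
                                 n_folds = 10L, seed = 1L, smote = TRUE, ...) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  lev <- sort(unique(labels))
  folds <- stratified_folds(labels, n_folds = n_folds, seed = seed)
  reports <- vector("list", n_folds)
  cms <- vector("list", n_folds)
  synthetic_in_test <- integer(n_folds)
  smote_counts <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    x_tr <- x[train_idx, , drop = FALSE]
    y_tr <- labels[train_idx]
    syn_flag <- rep(FALSE, length(train_idx))
    if (smote) {
      bal <- balance_training_set(x_tr, y_tr, seed = seed + f)
      x_tr <- bal$x
      y_tr <- bal$labels
      syn_flag <- bal$synthetic
    }
    # structural audit: synthetic rows exist only inside the training
    # partition built after the split; the test fold indexes original rows
    synthetic_in_test[f] <- sum(syn_flag[match(test_idx, train_idx)],
                                na.rm = TRUE)
    smote_counts[[f]] <- table(factor(y_tr, levels = lev), syn_flag)
    nz <- .fit_normalizer(x_tr)
    pred <- with_seed(seed + 1000L + f, {
      fit_predict_classifier(classifier, .apply_normalizer(x_tr, nz), y_tr,
                             .apply_normalizer(x[test_idx, , drop = FALSE], nz),
                             ...)
    })
    cms[[f]] <- confusion_matrix(labels[test_idx], pred, levels = lev)
    reports[[f]] <- compute_metrics(cms[[f]])
  }
  mean_report <- list(
    accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
    sensitivity = mean(vapply(reports, `[[`, numeric(1), "sensitivity")),
    specificity = mean(vapply(reports, `[[`, numeric(1), "specificity")),
    f1 = mean(vapply(reports, `[[`, numeric(1), "f1"))
  )
  class(mean_report) <- "metric_report"
  structure(list(
    classifier = classifier,
    folds = folds,
    fold_reports = reports,
    confusion_matrices = cms,
    mean_report = mean_report,
    synthetic_in_test = synthetic_in_test,
    smote_counts = smote_counts
  ), class = "class_experiment")
}

#' @export
print.class_experiment <- function(x, ...) {
  cat(sprintf("%d-fold stratified experiment, classifier '%s'\n",
              length(x$folds), x$classifier))
  cat("mean: ")
  print(x$mean_report)
  invisible(x)
}

#' @export
summary.class_experiment <- function(object, ...) {
  print(object)
  accs <- vapply(object$fold_reports, `[[`, numeric(1), "accuracy")
  cat("per-fold accuracy (%):", paste(sprintf("%.1f", accs), collapse = " "),
      "\n")
  cat("synthetic instances found in test folds:",
      sum(object$synthetic_in_test), "\n")
  invisible(object)
}
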