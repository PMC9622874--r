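#' Stratified k-fold cross-validation of the drug classifier
#'
#' Folds are stratified by class so that each test fold keeps (as closely as
#' possible) the overall 24:16-style class balance; every drug is tested
#' exactly once. The overall accuracy is pooled over folds
#' (correct predictions / all drugs); the mean of the fold accuracies is
#' reported alongside, since either reading is found in practice.
#'
#' @param m feature matrix over F (run [select_features()] first, as the
#'   original workflow selects features once on the full labeled set).
#' @param labels class labels; see [ttest_filter()].
#' @param n_folds number of folds (each class must have at least `n_folds`
#'   members).
#' @param seed RNG seed for fold assignment and forest fits.
#' @param n_trees forest size per fold.
#' @return An object of class `cv_report`: `fold_accuracies`,
#'   `overall_accuracy` (pooled), `mean_fold_accuracy`, `confusion`
#'   (2x2 matrix, truth in rows), `per_class` (precision/recall/F1),
#'   `n_folds`, `seed`, and the pooled `predictions`.
#' @export
#' @examples
#' sim <- simulate_descriptors(synthetic_spec(seed = 3, descriptors = list(
#'   delta = 6, n_constant = 0, n_correlated_pairs = 0,
#'   n_low_entropy = 0, n_noise = 4)))
#' cv <- cross_validate(sim$matrix[, sim$truth$informative], sim$labels,
#'                      seed = 3)
#' cv$overall_accuracy
cross_validate <- function(m, labels, n_folds = 5, seed = 1, n_trees = 100) {
  labels <- align_labels(m, labels)
  stopifnot(n_folds >= 2)
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("stratification infeasible: a class has fewer than n_folds drugs")
  }
  if (anyNA(m)) stop("cross-validation matrix has missing values")
  set.seed(stage_seed(seed, "cv_folds"))
  fold <- integer(nrow(m))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  pred <- factor(rep(NA_character_, nrow(m)), levels = levels(labels))
  fold_acc <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    set.seed(stage_seed(seed, paste0("cv_fit_", k)))
    fit <- randomForest::randomForest(m[!test, , drop = FALSE], labels[!test],
                                      ntree = n_trees)
    pred[test] <- predict(fit, m[test, , drop = FALSE])
    fold_acc[k] <- mean(pred[test] == labels[test])
  }
  confusion <- table(truth = labels, predicted = pred)
  per_class <- t(vapply(levels(labels), function(cl) {
    tp <- confusion[cl, cl]
    prec <- tp / sum(confusion[, cl])
    rec <- tp / sum(confusion[cl, ])
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else NA_real_
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  out <- list(fold_accuracies = fold_acc,
              overall_accuracy = mean(pred == labels),
              mean_fold_accuracy = mean(fold_acc),
              confusion = confusion,
              per_class = per_class,
              n_folds = as.integer(n_folds),
              seed = as.integer(seed),
              predictions = stats::setNames(pred, rownames(m)))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n",
              x$n_folds, x$seed))
  cat("  fold accuracies :",
      paste(sprintf("%.3f", x$fold_accuracies), collapse = " "), "\n")
  cat(sprintf("  overall accuracy: %.3f (pooled), %.3f (mean of folds)\n",
              x$overall_accuracy, x$mean_fold_accuracy))
  cat("  per-class precision / recall / F1:\n")
  print(round(x$per_class, 3))
  cat("  confusion matrix (truth in rows):\n")
  print(x$confusion)
  invisible(x)
}

#' @rdname cross_validate
#' @param x a `cv_report`.
#' @param path output TSV path (one row per fold plus summary rows).
#' @export
write_cv_report <- function(x, path) {
  stopifnot(inherits(x, "cv_report"))
  df <- data.frame(
    metric = c(paste0("fold_", seq_along(x$fold_accuracies), "_accuracy"),
               "overall_accuracy", "mean_fold_accuracy",
               paste0(rep(rownames(x$per_class), each = 3), "_",
                      rep(colnames(x$per_class), 2))),
    value = c(x$fold_accuracies, x$overall_accuracy, x$mean_fold_accuracy,
              as.vector(t(x$per_class))),
    stringsAsFactors = FALSE
  )
  write_report_tsv(df, path)
}
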