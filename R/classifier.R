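#' Out-of-bag error versus number of trees
#'
#' Fits a forest of `max_trees` trees and reads the cumulative out-of-bag
#' error after each tree. The chosen tree count is the smallest whose OOB
#' error is within `tolerance` of the curve minimum — a precise version of
#' the usual "error/forest-size trade-off" reading of the OOB curve.
#'
#' @param m numeric feature matrix (drugs x selected descriptors).
#' @param labels class factor; see [ttest_filter()] for accepted forms.
#' @param max_trees largest forest size probed (>= 1).
#' @param seed RNG seed for the bootstrap draws.
#' @param tolerance acceptable excess over the minimum OOB error.
#' @return An object of class `oob_curve`: data frame `curve` with columns
#'   `n_trees`, `oob_error`; `chosen_n_trees`; `tolerance`; `seed`.
#' @export
oob_curve <- function(m, labels, max_trees = 500, seed = 1, tolerance = 0.005) {
  labels <- align_labels(m, labels)
  if (any(table(labels) < 2L)) stop("each class needs at least 2 drugs")
  stopifnot(max_trees >= 1)
  set.seed(seed)
  fit <- randomForest::randomForest(m, labels, ntree = max_trees)
  err <- fit$err.rate[, "OOB"]
  chosen <- min(which(err <= min(err) + tolerance))
  out <- list(curve = data.frame(n_trees = seq_along(err),
                                 oob_error = unname(err)),
              chosen_n_trees = chosen, tolerance = tolerance, seed = seed)
  class(out) <- "oob_curve"
  out
}

#' @export
print.oob_curve <- function(x, ...) {
  cat(sprintf("OOB curve over %d trees: min error %.3f, chosen n_trees = %d (tolerance %.3f)\n",
              nrow(x$curve), min(x$curve$oob_error), x$chosen_n_trees,
              x$tolerance))
  invisible(x)
}

#' Fit the random-forest drug classifier
#'
#' The central model of the workflow: a random forest over the significant
#' descriptor set F separating therapeutic (positive) from exacerbating
#' (negative) drugs. When `x` is a full descriptor matrix the four-stage
#' cascade ([select_features()]) is run first; pass `select = FALSE` if `x`
#' is already restricted to F. The forest size defaults to the
#' configuration's 100 trees; `n_trees = "auto"` instead takes the smallest
#' forest within 0.005 of the minimum OOB error (see [oob_curve()]).
#'
#' @param x descriptor matrix (drugs in rows).
#' @param labels a `labeled_drugs` object, or a factor/character vector of
#'   `negative`/`positive` named by drug id or aligned with `x`'s rows.
#' @param config a [pipeline_config()].
#' @param select run the feature-selection cascade on `x` first?
#' @param n_trees forest size; a number, `NULL` (use `config$n_trees`) or
#'   `"auto"`.
#' @param max_trees search limit used when `n_trees = "auto"`.
#' @param seed RNG seed; defaults to the configuration seed.
#' @return An object of class `drug_classifier` with components `forest`
#'   (the fitted [randomForest::randomForest]), `features` (F, in order),
#'   `cascade` (the `feature_cascade`, or `NULL`), `oob` (an `oob_curve`),
#'   `training` (the training matrix over F), `labels`, `n_trees`, `seed`.
#' @export
#' @examples
#' sim <- simulate_descriptors(synthetic_spec(seed = 7, descriptors = list(
#'   n_constant = 2, n_correlated_pairs = 2, n_low_entropy = 2, n_noise = 8)))
#' fit <- drug_classifier(sim$matrix, sim$labels, seed = 7)
#' fit
#' head(predict(fit, sim$matrix))
drug_classifier <- function(x, labels, config = pipeline_config(),
                            select = TRUE, n_trees = NULL, max_trees = 500,
                            seed = config$rng_seed) {
  stopifnot(is.matrix(x))
  labels_f <- align_labels(x, labels)
  cascade <- NULL
  if (select) {
    cascade <- select_features(x, labels_f, config)
    xf <- cascade$matrix
  } else {
    xf <- x
  }
  if (!ncol(xf)) stop("no features left to train on")
  if (anyNA(xf)) stop("training matrix has missing values after selection")
  oob <- oob_curve(xf, labels_f, max_trees = max_trees, seed = seed)
  if (is.null(n_trees)) n_trees <- config$n_trees
  if (identical(n_trees, "auto")) n_trees <- oob$chosen_n_trees
  set.seed(seed)
  forest <- randomForest::randomForest(xf, labels_f, ntree = n_trees,
                                       importance = TRUE)
  out <- list(forest = forest, features = colnames(xf), cascade = cascade,
              oob = oob, training = xf, labels = labels_f,
              n_trees = as.integer(n_trees), seed = as.integer(seed),
              class_counts = table(labels_f), call = match.call())
  class(out) <- "drug_classifier"
  out
}

#' Predict class probabilities (or classes) for drugs
#'
#' Prediction is deterministic given the fitted model. The input must carry
#' every feature of F (an informative error names any missing one) and no
#' missing values among them; extra columns are ignored and order is fixed
#' internally.
#'
#' @param object a `drug_classifier`.
#' @param newdata descriptor matrix containing the model features.
#' @param type `"prob"` for a two-column probability matrix (columns
#'   `negative`, `positive`, rows summing to 1) or `"class"`.
#' @param ... unused.
#' @export
predict.drug_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  missing_feats <- setdiff(object$features, colnames(newdata))
  if (length(missing_feats)) {
    stop("newdata lacks model feature(s): ",
         paste(missing_feats, collapse = ", "))
  }
  nd <- newdata[, object$features, drop = FALSE]
  if (anyNA(nd)) {
    bad <- rownames(nd)[apply(nd, 1L, anyNA)]
    stop("missing descriptor values for drug(s): ",
         paste(bad, collapse = ", "))
  }
  predict(object$forest, nd, type = if (type == "prob") "prob" else "response")
}

#' @export
print.drug_classifier <- function(x, ...) {
  cat("Random-forest drug classifier\n")
  cat(sprintf("  training drugs   %d (%d negative / %d positive)\n",
              sum(x$class_counts), x$class_counts[["negative"]],
              x$class_counts[["positive"]]))
  cat(sprintf("  features (F)     %d: %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  trees            %d (OOB error %.3f; curve minimum %.3f)\n",
              x$n_trees, x$forest$err.rate[x$n_trees, "OOB"],
              min(x$oob$curve$oob_error)))
  cat(sprintf("  seed             %d\n", x$seed))
  invisible(x)
}

#' @export
summary.drug_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$cascade)) {
    cat("\n")
    print(object$cascade)
  }
  imp <- randomForest::importance(object$forest, type = 2L)
  cat("\nFeature importance (mean decrease in node impurity)\n")
  print(round(imp[order(-imp[, 1L]), 1L, drop = FALSE], 3))
  invisible(object)
}

#' @rdname oob_curve
#' @param x a `drug_classifier` or `oob_curve`.
#' @param ... passed to [plot()].
#' @export
plot.drug_classifier <- function(x, ...) plot(x$oob, ...)

#' @export
plot.oob_curve <- function(x, ...) {
  plot(x$curve$n_trees, x$curve$oob_error, type = "l",
       xlab = "number of trees", ylab = "OOB error", ...)
  graphics::abline(v = x$chosen_n_trees, lty = 2)
  invisible(x)
}

#' @rdname oob_curve
#' @param path output TSV path for the tree-count/error curve.
#' @export
write_oob_curve <- function(x, path) {
  if (inherits(x, "drug_classifier")) x <- x$oob
  stopifnot(inherits(x, "oob_curve"))
  write_report_tsv(x$curve, path)
}
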