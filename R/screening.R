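#' Remove very small molecules by atom count
#'
#' Drugs with fewer than `mu` atoms are too small to carry the descriptor
#' profile of the training chemistry and are removed before the
#' applicability-domain filters.
#'
#' @param m descriptor matrix carrying an atom-count column (see
#'   [descriptor_matrix()]).
#' @param mu minimum atom count retained (`nATOM >= mu` kept).
#' @param natom_column column name; defaults to the matrix attribute.
#' @return A list: `matrix` (retained rows, attribute preserved),
#'   `removed` (drug ids).
#' @export
natom_filter <- function(m, mu = 7, natom_column = attr(m, "natom_column")) {
  stopifnot(is.matrix(m))
  if (is.null(natom_column) || !(natom_column %in% colnames(m))) {
    stop("atom-count column not found; set natom_column")
  }
  natoms <- m[, natom_column]
  keep <- !is.na(natoms) & natoms >= mu
  out <- m[keep, , drop = FALSE]
  attr(out, "natom_column") <- natom_column
  list(matrix = out, removed = rownames(m)[!keep])
}

#' Warning leverage threshold of the applicability domain
#'
#' The standard QSAR cut `h* = multiplier * p / n` with `p` the number of
#' model variables plus one and `n` the number of compounds in the leverage
#' basis.
#'
#' @param n_features number of model features (|F|).
#' @param n_compounds number of compounds in the basis matrix.
#' @param multiplier conventionally 3.
#' @return The scalar threshold `h*`.
#' @export
#' @examples
#' warning_leverage(6, 2304)  # 3 * 7 / 2304 = 0.0091
warning_leverage <- function(n_features, n_compounds, multiplier = 3) {
  stopifnot(n_features >= 0, multiplier >= 0)
  if (n_compounds <= 0) stop("leverage basis has no compounds")
  multiplier * (n_features + 1) / n_compounds
}

#' Leverage of query molecules against a descriptor basis
#'
#' Computes `h_i = x_i' (X'X)^-1 x_i` for each query row against the basis
#' matrix `X` (no intercept column is appended: the formula acts on the raw
#' descriptor rows). For the rows of a full-column-rank `X` itself these are
#' the hat-matrix diagonals: each lies in `[0, 1]` and they sum to the number
#' of columns. A rank-deficient `X'X` falls back to the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param x numeric vector (one molecule) or matrix of query rows with
#'   exactly the columns of `X`.
#' @param X basis descriptor matrix.
#' @return Numeric vector of leverages, one per query row.
#' @export
#' @examples
#' X <- cbind(x = c(1, 2))
#' leverage(c(x = 1), X)  # 1 / (1^2 + 2^2) = 0.2
leverage <- function(x, X) {
  stopifnot(is.matrix(X))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (ncol(x) != ncol(X)) stop("query and basis column dimensions differ")
  if (!is.null(colnames(x)) && !is.null(colnames(X)) &&
      !identical(colnames(x), colnames(X))) {
    if (!all(colnames(X) %in% colnames(x))) {
      stop("query lacks basis column(s): ",
           paste(setdiff(colnames(X), colnames(x)), collapse = ", "))
    }
    x <- x[, colnames(X), drop = FALSE]
  }
  xtx <- crossprod(X)
  inv <- tryCatch(solve(xtx), error = function(e) {
    warning("X'X is singular; using the Moore-Penrose pseudo-inverse",
            call. = FALSE)
    MASS::ginv(xtx)
  })
  unname(rowSums((x %*% inv) * x))
}

#' One-class SVM novelty filter around the training chemistry
#'
#' Fits a radial-basis one-class SVM on the training drugs (standardized
#' with the training mean and SD) and retains the screened drugs it
#' classifies as in-distribution. The default kernel width is
#' `gamma = 1 / (w * pooled variance)` of the standardized training block
#' (so effectively `1/w`), with `w` the number of features.
#'
#' @param train training matrix over the model features.
#' @param screen screened matrix over the same features.
#' @param nu one-class SVM nu (upper bound on the training rejection rate).
#' @param gamma RBF width; `NULL` for the pooled-variance default.
#' @return A list: `retained` (screen drug ids), `removed`, `model`.
#' @export
ocsvm_filter <- function(train, screen, nu = 0.1, gamma = NULL) {
  stopifnot(is.matrix(train), is.matrix(screen),
            identical(colnames(train), colnames(screen)))
  if (anyNA(train) || anyNA(screen)) stop("one-class SVM input has missing values")
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  if (any(sdv == 0)) {
    stop("degenerate training matrix: zero-variance feature '",
         colnames(train)[which(sdv == 0)[1L]], "'")
  }
  tr <- scale(train, center = mu, scale = sdv)
  sc <- scale(screen, center = mu, scale = sdv)
  if (is.null(gamma)) gamma <- 1 / (ncol(tr) * mean(apply(tr, 2L, var)))
  model <- e1071::svm(tr, y = NULL, type = "one-classification",
                      kernel = "radial", nu = nu, gamma = gamma,
                      scale = FALSE)
  ok <- if (nrow(sc)) as.logical(predict(model, sc)) else logical()
  list(retained = rownames(screen)[ok], removed = rownames(screen)[!ok],
       model = model)
}

#' Rank screened drugs into candidate and warning tables
#'
#' Each drug is assigned to the class with the larger predicted probability;
#' only drugs whose winning probability meets `threshold` are reported,
#' sorted by decreasing probability within class. Positives are the
#' repurposing candidates, negatives the adverse-drug warnings.
#'
#' @param model a [drug_classifier()].
#' @param screen descriptor matrix of the (already domain-filtered) library.
#' @param threshold minimum winning-class probability, in (0.5, 1].
#' @return A data frame of class `candidate_table` with columns `drug_id`,
#'   `predicted_label`, `probability`.
#' @export
rank_candidates <- function(model, screen, threshold = 0.95) {
  stopifnot(inherits(model, "drug_classifier"))
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  if (!nrow(screen)) {
    out <- data.frame(drug_id = character(), predicted_label = character(),
                      probability = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    return(out)
  }
  pr <- predict(model, screen, type = "prob")
  win <- ifelse(pr[, "positive"] >= pr[, "negative"], "positive", "negative")
  p_win <- pmax(pr[, "positive"], pr[, "negative"])
  keep <- p_win >= threshold
  out <- data.frame(drug_id = rownames(screen)[keep],
                    predicted_label = win[keep],
                    probability = unname(p_win[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$predicted_label == "negative", -out$probability,
                   out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Screen a drug library through the applicability-domain cascade
#'
#' Runs the full screening chain against a fitted classifier: (1) atom-count
#' rule, (2) removal of drugs missing any model feature value, (3) leverage
#' against the warning leverage `h* = 3(p+1)/n`, (4) radial one-class SVM,
#' (5) probability ranking. Stage removals are disjoint and reconcile
#' exactly with the retained set.
#'
#' By default the leverage basis is the screened library itself
#' (`ad_basis = "screening"`), which reproduces the published
#' warning-leverage arithmetic; `ad_basis = "training"` gives the textbook
#' convention of measuring distance from the training matrix.
#'
#' @param model a [drug_classifier()].
#' @param library_matrix descriptor matrix of the external library,
#'   including the atom-count column.
#' @param config a [pipeline_config()].
#' @return An object of class `screening_report`: attrition ids per stage
#'   (`removed_small`, `removed_missing`, `removed_high_leverage`,
#'   `removed_ocsvm`), `h_star`, `leverages`, `retained`, `candidates`
#'   (a `candidate_table`), `n_input`, `seed`.
#' @export
screen_library <- function(model, library_matrix, config = pipeline_config()) {
  stopifnot(inherits(model, "drug_classifier"), is.matrix(library_matrix))
  n_input <- nrow(library_matrix)

  # 1. atom-count rule
  s1 <- natom_filter(library_matrix, mu = config$natom_min)

  # 2. drugs missing any model feature value
  feats <- model$features
  missing_feats <- setdiff(feats, colnames(s1$matrix))
  if (length(missing_feats)) {
    stop("library lacks model feature(s): ",
         paste(missing_feats, collapse = ", "))
  }
  xf <- s1$matrix[, feats, drop = FALSE]
  has_na <- apply(xf, 1L, anyNA)
  removed_missing <- rownames(xf)[has_na]
  xf <- xf[!has_na, , drop = FALSE]

  # 3. leverage against the warning leverage
  basis <- if (config$ad_basis == "screening") xf else model$training
  h_star <- warning_leverage(length(feats), nrow(basis),
                             config$leverage_multiplier)
  h <- if (nrow(xf)) leverage(xf, basis) else numeric()
  names(h) <- rownames(xf)
  high <- h > h_star
  removed_leverage <- rownames(xf)[high]
  xf <- xf[!high, , drop = FALSE]

  # 4. one-class SVM around the training chemistry
  if (nrow(xf)) {
    oc <- ocsvm_filter(model$training, xf, nu = config$ocsvm_nu,
                       gamma = config$ocsvm_gamma)
    removed_ocsvm <- oc$removed
    xf <- xf[!(rownames(xf) %in% removed_ocsvm), , drop = FALSE]
  } else {
    removed_ocsvm <- character()
  }

  # 5. probability ranking
  candidates <- rank_candidates(model, xf,
                                threshold = config$probability_threshold)

  out <- list(n_input = n_input,
              removed_small = s1$removed,
              removed_missing = removed_missing,
              h_star = h_star,
              leverages = h,
              removed_high_leverage = removed_leverage,
              removed_ocsvm = removed_ocsvm,
              retained = rownames(xf),
              candidates = candidates,
              ad_basis = config$ad_basis,
              seed = config$rng_seed)
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Applicability-domain screening\n")
  cat(sprintf("  library drugs          %d\n", x$n_input))
  cat(sprintf("  - atom-count rule      %d removed\n", length(x$removed_small)))
  cat(sprintf("  - missing features     %d removed\n", length(x$removed_missing)))
  cat(sprintf("  - leverage > h*=%.4f   %d removed (basis: %s)\n",
              x$h_star, length(x$removed_high_leverage), x$ad_basis))
  cat(sprintf("  - one-class SVM        %d removed\n", length(x$removed_ocsvm)))
  cat(sprintf("  retained in domain     %d\n", length(x$retained)))
  cat(sprintf("  candidates >= threshold: %d positive, %d negative\n",
              sum(x$candidates$predicted_label == "positive"),
              sum(x$candidates$predicted_label == "negative")))
  invisible(x)
}

#' @rdname screen_library
#' @param x a `screening_report`.
#' @param path output TSV path (per-drug stage outcome and leverage).
#' @export
write_screening_report <- function(x, path) {
  stopifnot(inherits(x, "screening_report"))
  ids <- c(x$removed_small, x$removed_missing, x$removed_high_leverage,
           x$removed_ocsvm, x$retained)
  stage <- rep(c("removed_small_molecule", "removed_missing_features",
                 "removed_high_leverage", "removed_ocsvm", "retained"),
               c(length(x$removed_small), length(x$removed_missing),
                 length(x$removed_high_leverage), length(x$removed_ocsvm),
                 length(x$retained)))
  df <- data.frame(drug_id = ids, stage = stage,
                   leverage = unname(x$leverages[ids]),
                   stringsAsFactors = FALSE)
  write_report_tsv(df, path)
}
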