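#' Remove constant descriptors
#'
#' Drops every column with a single distinct non-missing value (missing
#' entries are ignored when judging constancy). Constant descriptors carry no
#' class information and break the correlation stage.
#'
#' @param m a descriptor matrix (molecules x descriptors).
#' @return A list: `matrix` (pruned), `removed` (column names).
#' @export
remove_constant <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  n_distinct <- apply(m, 2L, function(v) length(unique(v[!is.na(v)])))
  removed <- colnames(m)[n_distinct <= 1L]
  if (length(removed) == ncol(m)) stop("every descriptor column is constant")
  list(matrix = m[, setdiff(colnames(m), removed), drop = FALSE],
       removed = removed)
}

#' Prune highly correlated descriptors
#'
#' Iterative pairwise heuristic over the absolute Pearson correlation matrix
#' (pairwise-complete observations): every unordered pair exceeding `cutoff`
#' flags the member with the larger mean absolute correlation for removal,
#' without recomputing correlations after each drop. This reproduces the
#' non-exact mode of the correlation filter commonly used for descriptor
#' matrices, including its documented column-order dependence under ties.
#'
#' @param m descriptor matrix with no constant columns.
#' @param cutoff absolute correlation above which a pair is offending,
#'   in (0, 1].
#' @return A list: `matrix`, `removed`.
#' @export
prune_correlated <- function(m, cutoff = 0.9) {
  stopifnot(is.matrix(m))
  if (cutoff <= 0 || cutoff > 1) stop("correlation cutoff must be in (0, 1]")
  if (ncol(m) < 2L) return(list(matrix = m, removed = character()))
  cm <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(cm)) {
    stop("correlation undefined for some descriptor pair ",
         "(constant column or no overlapping observations)")
  }
  avg_rank <- as.numeric(as.factor(colMeans(abs(cm))))
  cm[lower.tri(cm, diag = TRUE)] <- NA
  offending <- which(abs(cm) > cutoff)
  if (!length(offending)) return(list(matrix = m, removed = character()))
  col_i <- ceiling(offending / nrow(cm))
  row_i <- offending - (col_i - 1L) * nrow(cm)
  drop_col <- avg_rank[col_i] > avg_rank[row_i]
  removed_idx <- unique(c(col_i[drop_col], row_i[!drop_col]))
  removed <- colnames(m)[sort(removed_idx)]
  list(matrix = m[, setdiff(colnames(m), removed), drop = FALSE],
       removed = removed)
}

#' Plug-in Shannon entropy of a descriptor over an equal-width histogram
#'
#' Values are binned into `bins` equal-width intervals spanning the observed
#' range; the entropy of the bin frequencies is returned in nats. A column
#' with a single distinct value has entropy 0; missing values are ignored.
#'
#' @param v numeric vector.
#' @param bins number of histogram bins (>= 2).
#' @return Entropy in nats (log base e).
#' @export
#' @examples
#' shannon_entropy(rep(1:10, 4))     # uniform over 10 bins: log(10)
#' shannon_entropy(rep(c(0, 1), 20)) # two equal bins: log(2)
shannon_entropy <- function(v, bins = 10) {
  stopifnot(bins >= 2)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  counts <- tabulate(cut(v, breaks, include.lowest = TRUE, labels = FALSE),
                     nbins = bins)
  p <- counts[counts > 0] / length(v)
  -sum(p * log(p))
}

#' Remove low-entropy descriptors
#'
#' @param m descriptor matrix.
#' @param threshold entropy floor in nats; columns below it are removed.
#' @param bins histogram bins for [shannon_entropy()].
#' @return A list: `matrix`, `removed`, `entropies` (named, all input
#'   columns).
#' @export
entropy_filter <- function(m, threshold = 1.5, bins = 10) {
  stopifnot(is.matrix(m))
  ent <- apply(m, 2L, shannon_entropy, bins = bins)
  removed <- colnames(m)[ent < threshold]
  list(matrix = m[, setdiff(colnames(m), removed), drop = FALSE],
       removed = removed, entropies = ent)
}

#' Select class-separating descriptors by two-sample t-test
#'
#' Tests each descriptor for a mean difference between the positive and
#' negative drug classes; descriptors with p below `alpha` are selected.
#' Welch's unequal-variance test is the default; rows missing a value are
#' excluded from that descriptor's test only. Descriptors that are constant
#' within the pooled data yield p = 1. No multiplicity correction is applied
#' by default (`p_adjust = "none"`), matching the raw p < 0.05 rule of the
#' original cascade.
#'
#' @param m descriptor matrix.
#' @param labels factor of classes (`negative`/`positive`) named by or
#'   aligned with the rows of `m`, or a `labeled_drugs` object.
#' @param alpha significance level.
#' @param var_equal use the pooled-variance test.
#' @param p_adjust a [stats::p.adjust] method applied before thresholding.
#' @return A list: `matrix` (selected columns), `selected`, `removed`,
#'   `p_values` (named, all input columns).
#' @export
ttest_filter <- function(m, labels, alpha = 0.05, var_equal = FALSE,
                         p_adjust = "none") {
  labels <- align_labels(m, labels)
  if (any(table(labels) < 2L)) {
    stop("each class needs at least 2 drugs for the t-test stage")
  }
  pos <- labels == "positive"
  pv <- apply(m, 2L, function(v) {
    a <- v[pos & !is.na(v)]
    b <- v[!pos & !is.na(v)]
    if (length(a) < 2L || length(b) < 2L) return(1)
    tryCatch(t.test(a, b, var.equal = var_equal)$p.value,
             error = function(e) 1)  # essentially-constant data
  })
  pv_adj <- stats::p.adjust(pv, method = p_adjust)
  selected <- colnames(m)[pv_adj < alpha]
  list(matrix = m[, selected, drop = FALSE], selected = selected,
       removed = setdiff(colnames(m), selected), p_values = pv)
}

# internal: coerce labels to a factor aligned with the matrix rows
align_labels <- function(m, labels) {
  if (inherits(labels, "labeled_drugs")) labels <- drug_classes(labels)
  if (!is.null(names(labels))) {
    idx <- match(norm_id(rownames(m)), norm_id(names(labels)))
    if (anyNA(idx)) {
      stop("labels missing for drug(s): ",
           paste(rownames(m)[is.na(idx)], collapse = ", "))
    }
    labels <- labels[idx]
  } else if (length(labels) != nrow(m)) {
    stop("labels must be named or match the number of matrix rows")
  }
  factor(as.character(labels), levels = c("negative", "positive"))
}

#' The four-stage descriptor selection cascade
#'
#' Applies, in order: constant-column removal, correlation pruning
#' ([prune_correlated()]), the entropy floor ([entropy_filter()]) and the
#' class t-test ([ttest_filter()]). The four removal lists plus the selected
#' set partition the input descriptor names exactly.
#'
#' @param m descriptor matrix over the labeled training drugs.
#' @param labels class labels; see [ttest_filter()].
#' @param config a [pipeline_config()] supplying the cutoff, entropy
#'   threshold/bins, alpha, t-test variant and p-adjust method.
#' @return An object of class `feature_cascade`: `selected` (the significant
#'   feature set F, in input column order), `matrix` (training rows restricted
#'   to F), removal lists `removed_constant`, `removed_correlated`,
#'   `removed_low_entropy`, `removed_nonsignificant`, plus per-feature
#'   `entropies` and `p_values` and `n_input_features`.
#' @export
#' @examples
#' sim <- simulate_descriptors(synthetic_spec(seed = 1, descriptors = list(
#'   n_constant = 3, n_correlated_pairs = 3, n_low_entropy = 3, n_noise = 10)))
#' sel <- select_features(sim$matrix, sim$labels)
#' sel$selected
select_features <- function(m, labels, config = pipeline_config()) {
  stopifnot(is.matrix(m))
  s1 <- remove_constant(m)
  s2 <- prune_correlated(s1$matrix, cutoff = config$correlation_cutoff)
  s3 <- entropy_filter(s2$matrix, threshold = config$entropy_threshold,
                       bins = config$entropy_bins)
  s4 <- ttest_filter(s3$matrix, labels, alpha = config$alpha,
                     var_equal = config$t_var_equal,
                     p_adjust = config$p_adjust)
  out <- list(
    n_input_features = ncol(m),
    removed_constant = s1$removed,
    removed_correlated = s2$removed,
    removed_low_entropy = s3$removed,
    removed_nonsignificant = s4$removed,
    selected = s4$selected,
    matrix = s4$matrix,
    entropies = s3$entropies,
    p_values = s4$p_values
  )
  class(out) <- "feature_cascade"
  out
}

#' @rdname select_features
#' @param x a `feature_cascade`.
#' @param path output TSV path; one row per input feature with the stage at
#'   which it was removed (or `selected`), its entropy and p-value where
#'   computed.
#' @export
write_feature_report <- function(x, path) {
  stopifnot(inherits(x, "feature_cascade"))
  all_feats <- c(x$removed_constant, x$removed_correlated,
                 x$removed_low_entropy, x$removed_nonsignificant, x$selected)
  stage <- rep(c("constant", "correlated", "low_entropy", "nonsignificant",
                 "selected"),
               c(length(x$removed_constant), length(x$removed_correlated),
                 length(x$removed_low_entropy),
                 length(x$removed_nonsignificant), length(x$selected)))
  df <- data.frame(feature = all_feats, stage = stage,
                   entropy = unname(x$entropies[all_feats]),
                   p_value = unname(x$p_values[all_feats]),
                   stringsAsFactors = FALSE)
  write_report_tsv(df, path)
}

#' @export
print.feature_cascade <- function(x, ...) {
  cat("Descriptor selection cascade\n")
  cat(sprintf("  input features     %d\n", x$n_input_features))
  cat(sprintf("  - constant         %d\n", length(x$removed_constant)))
  cat(sprintf("  - correlated       %d\n", length(x$removed_correlated)))
  cat(sprintf("  - low entropy      %d\n", length(x$removed_low_entropy)))
  cat(sprintf("  - non-significant  %d\n", length(x$removed_nonsignificant)))
  cat(sprintf("  selected (F)       %d: %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
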