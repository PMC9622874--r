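#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one validated object.
#' Defaults reproduce the study conditions: hub tiers accumulated up to 15
#' nodes, Pearson cutoff 0.9 for descriptor pruning, Shannon-entropy floor of
#' 1.5 nats over a 10-bin histogram, raw two-sample t-test at alpha = 0.05,
#' atom-count floor of 7, warning leverage 3(p+1)/n, a 100-tree forest with
#' 5-fold stratified cross-validation, and a 0.95 class-probability threshold
#' for screening candidates.
#'
#' @param hub_max_nodes maximum cumulative tier size for hub selection.
#' @param correlation_cutoff absolute Pearson correlation above which one of a
#'   descriptor pair is pruned.
#' @param entropy_threshold minimum plug-in Shannon entropy, in nats.
#' @param entropy_bins number of equal-width histogram bins for the entropy
#'   estimate.
#' @param alpha significance level of the two-sample t-test stage.
#' @param natom_min smallest atom count retained by the screening filter
#'   (drugs with fewer atoms are removed).
#' @param leverage_multiplier multiplier in the warning leverage
#'   `multiplier * (p + 1) / n`.
#' @param probability_threshold minimum class probability for a screened drug
#'   to be reported as a candidate.
#' @param n_folds number of cross-validation folds.
#' @param n_trees number of trees in the random forest.
#' @param rng_seed integer seed recorded in every report.
#' @param ad_basis `"screening"` (default) computes leverage against the
#'   screened library itself, which reproduces the published warning-leverage
#'   arithmetic; `"training"` uses the textbook QSAR convention of the
#'   training matrix.
#' @param ocsvm_nu,ocsvm_gamma one-class SVM parameters; `ocsvm_gamma = NULL`
#'   uses `1 / (w * pooled variance)` of the standardized training block.
#' @param t_var_equal use the pooled-variance t-test instead of Welch.
#' @param p_adjust multiple-testing correction for the t-test stage; `"none"`
#'   (the study applies raw p < alpha) or any [stats::p.adjust] method.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @seealso [read_pipeline_config()], [run_all()]
#' @export
#' @examples
#' cfg <- pipeline_config(entropy_threshold = 2)
#' cfg$entropy_threshold
pipeline_config <- function(hub_max_nodes = 15,
                            correlation_cutoff = 0.9,
                            entropy_threshold = 1.5,
                            entropy_bins = 10,
                            alpha = 0.05,
                            natom_min = 7,
                            leverage_multiplier = 3,
                            probability_threshold = 0.95,
                            n_folds = 5,
                            n_trees = 100,
                            rng_seed = 1,
                            ad_basis = c("screening", "training"),
                            ocsvm_nu = 0.1,
                            ocsvm_gamma = NULL,
                            t_var_equal = FALSE,
                            p_adjust = "none") {
  ad_basis <- match.arg(ad_basis)
  stopifnot(
    hub_max_nodes >= 1,
    correlation_cutoff > 0, correlation_cutoff <= 1,
    entropy_threshold >= 0,
    entropy_bins >= 2,
    alpha > 0, alpha < 1,
    natom_min >= 0,
    leverage_multiplier >= 0,
    probability_threshold > 0.5, probability_threshold <= 1,
    n_folds >= 2,
    n_trees >= 1,
    ocsvm_nu > 0, ocsvm_nu < 1,
    is.null(ocsvm_gamma) || ocsvm_gamma > 0
  )
  cfg <- list(
    hub_max_nodes = as.integer(hub_max_nodes),
    correlation_cutoff = correlation_cutoff,
    entropy_threshold = entropy_threshold,
    entropy_bins = as.integer(entropy_bins),
    alpha = alpha,
    natom_min = as.integer(natom_min),
    leverage_multiplier = leverage_multiplier,
    probability_threshold = probability_threshold,
    n_folds = as.integer(n_folds),
    n_trees = as.integer(n_trees),
    rng_seed = as.integer(rng_seed),
    ad_basis = ad_basis,
    ocsvm_nu = ocsvm_nu,
    ocsvm_gamma = ocsvm_gamma,
    t_var_equal = isTRUE(t_var_equal),
    p_adjust = p_adjust
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML keys mirror the [pipeline_config()] argument names; unknown keys
#' are rejected so a typo cannot silently fall back to a default.
#'
#' @param path file path of the YAML configuration.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` object.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(v)) "<auto>" else format(v)))
  }
  invisible(x)
}
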