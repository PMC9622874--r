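#' Specification for the synthetic benchmark generator
#'
#' Describes data with the statistical structure every pipeline stage
#' assumes, with planted ground truth returned alongside. Defaults mirror
#' the study's dimensions: a 412-miRNA first network with 7 planted hubs, a
#' 40-drug effect table, a 40 x 1444 descriptor matrix with a 16/24 class
#' split and 6 informative columns separated by 3 pooled SDs, and a
#' 2474-drug screening library. Each block can be partially overridden; all
#' generation is a pure function of the spec (same spec + seed gives
#' byte-identical output).
#'
#' Block fields:
#' * `network`: `n_left`, `n_right`, `p_background`, `n_planted_hubs`,
#'   `hub_degree` (first layer); `n_right2`, `n_planted_hubs2`,
#'   `hub_degree2`, `p_background2` (second layer, whose left side are the
#'   first layer's planted hubs).
#' * `effects`: `n_drugs`, `n_lncrnas`, `contradiction_rate` (per-drug
#'   probability of planted mixed-sign edges), `positive_fraction`,
#'   `max_edges` per drug.
#' * `descriptors`: `n_pos`, `n_neg`, `n_informative`, `delta` (class
#'   separation in pooled SDs), `n_constant`, `n_correlated_pairs` (each
#'   pair = a base column plus a near-duplicate with |r| > 0.95),
#'   `n_low_entropy` (> 90% of mass in one histogram bin), `n_noise`
#'   (heavy-tailed log-normal), `missing_rate` (applied to noise columns).
#' * `screen`: `n_screen`, `outlier_fraction`, `outlier_distance`
#'   (Mahalanobis distance of planted far-outliers), `small_fraction`
#'   (drugs given an atom count below 7), `strong_fraction` (in-domain
#'   drugs planted at the positive-class centroid, i.e. clear repurposing
#'   candidates the screen should recover).
#'
#' @param seed integer seed.
#' @param network,effects,descriptors,screen named lists overriding the
#'   defaults of each block.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(seed = 1, effects = list(contradiction_rate = 0.3))
#' sp$effects$contradiction_rate
synthetic_spec <- function(seed = 1, network = list(), effects = list(),
                           descriptors = list(), screen = list()) {
  def <- list(
    network = list(n_left = 40, n_right = 412, p_background = 0.15,
                   n_planted_hubs = 7, hub_degree = 20,
                   n_right2 = 1700, n_planted_hubs2 = 11, hub_degree2 = 7,
                   p_background2 = 0.1),
    effects = list(n_drugs = 40, n_lncrnas = 4, contradiction_rate = 0,
                   positive_fraction = 0.4, max_edges = 3),
    descriptors = list(n_pos = 16, n_neg = 24, n_informative = 6, delta = 3,
                       n_constant = 293, n_correlated_pairs = 400,
                       n_low_entropy = 113, n_noise = 231, missing_rate = 0),
    screen = list(n_screen = 2474, outlier_fraction = 0.04,
                  outlier_distance = 10, small_fraction = 0.063,
                  strong_fraction = 0.02)
  )
  spec <- list(
    seed = as.integer(seed),
    network = utils::modifyList(def$network, network),
    effects = utils::modifyList(def$effects, effects),
    descriptors = utils::modifyList(def$descriptors, descriptors),
    screen = utils::modifyList(def$screen, screen)
  )
  with(spec$network, stopifnot(n_left >= 1, n_right >= 1,
                               p_background >= 0, p_background <= 1,
                               n_planted_hubs >= 0, n_planted_hubs <= n_right,
                               hub_degree >= 1, hub_degree <= n_left))
  with(spec$effects, stopifnot(n_drugs >= 0, n_lncrnas >= 2,
                               contradiction_rate >= 0, contradiction_rate <= 1,
                               positive_fraction >= 0, positive_fraction <= 1))
  with(spec$descriptors, stopifnot(n_pos + n_neg >= 4, n_informative >= 0,
                                   delta >= 0, n_constant >= 0,
                                   n_correlated_pairs >= 0, n_low_entropy >= 0,
                                   n_noise >= 0, missing_rate >= 0,
                                   missing_rate < 1))
  with(spec$screen, stopifnot(n_screen >= 0, outlier_fraction >= 0,
                              outlier_fraction <= 1, outlier_distance >= 0,
                              small_fraction >= 0, small_fraction <= 1,
                              strong_fraction >= 0,
                              outlier_fraction + strong_fraction <= 1))
  class(spec) <- "synthetic_spec"
  spec
}

#' Simulate the two layered bipartite interaction networks
#'
#' Planted hub nodes on the right side receive exactly `hub_degree` edges to
#' distinct left nodes; background right nodes receive independent edges
#' with probability `p_background` per left node. With zero background the
#' hub degrees are exact. The second layer reuses the first layer's planted
#' hubs as its left side.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `mrna_mirna` and `mirna_lncrna` (`interaction_edges`),
#'   `hubs_mirna` and `hubs_lncrna` (planted hub ids = ground truth).
#' @export
simulate_networks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "networks"))
  nw <- spec$network
  layer1 <- plant_bipartite(sprintf("P%03d", seq_len(nw$n_left)),
                            sprintf("M%04d", seq_len(nw$n_right)),
                            nw$p_background, nw$n_planted_hubs, nw$hub_degree,
                            "mrna_mirna")
  nw2_left <- layer1$hubs
  if (!length(nw2_left)) nw2_left <- sprintf("M%04d", seq_len(min(7, nw$n_right)))
  layer2 <- plant_bipartite(nw2_left,
                            sprintf("L%04d", seq_len(nw$n_right2)),
                            nw$p_background2, nw$n_planted_hubs2,
                            min(nw$hub_degree2, length(nw2_left)),
                            "mirna_lncrna")
  list(mrna_mirna = layer1$edges, mirna_lncrna = layer2$edges,
       hubs_mirna = layer1$hubs, hubs_lncrna = layer2$hubs)
}

# internal: one bipartite layer with planted right-side hubs
plant_bipartite <- function(left, right, p_bg, n_hubs, hub_degree, layer) {
  hubs <- if (n_hubs > 0) sample(right, n_hubs) else character()
  bg <- setdiff(right, hubs)
  hub_edges <- do.call(rbind, lapply(hubs, function(h) {
    data.frame(source = sample(left, hub_degree), target = h,
               stringsAsFactors = FALSE)
  }))
  bg_edges <- NULL
  if (p_bg > 0 && length(bg)) {
    hit <- which(matrix(runif(length(left) * length(bg)) < p_bg,
                        nrow = length(left)), arr.ind = TRUE)
    if (nrow(hit)) {
      bg_edges <- data.frame(source = left[hit[, 1L]],
                             target = bg[hit[, 2L]],
                             stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(hub_edges, bg_edges)
  if (is.null(edges) || !nrow(edges)) {
    stop("simulated layer has no edges; raise p_background or plant hubs")
  }
  list(edges = make_edges(edges, layer, path = "<simulated>"), hubs = hubs)
}

#' Simulate a drug effect table with planted contradictions
#'
#' Every lncRNA gets a shared disease direction; each drug is, with
#' probability `contradiction_rate`, given one therapeutic and one
#' exacerbating edge (to two different lncRNAs), and otherwise 1 to
#' `max_edges` edges of a uniform sign drawn with `positive_fraction`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `effects` (drug, lncrna, effect), `directions`, `truth`
#'   (data frame drug/label with label in positive/negative/contradictory).
#' @export
simulate_effect_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "effects"))
  ef <- spec$effects
  lnc <- sprintf("LNC%02d", seq_len(ef$n_lncrnas))
  dir <- sample(c("up", "down"), ef$n_lncrnas, replace = TRUE)
  directions <- data.frame(lncrna = lnc, direction_dm = dir,
                           direction_ad = dir, stringsAsFactors = FALSE)
  # effect verb achieving a wanted sign against a direction
  verb_for <- function(direction, sign) {
    therapeutic <- sign == "therapeutic"
    up <- direction == "up"
    ifelse(xor(up, therapeutic), "increase", "decrease")
  }
  drugs <- sprintf("DRUG%03d", seq_len(ef$n_drugs))
  contradictory <- runif(ef$n_drugs) < ef$contradiction_rate
  rows <- vector("list", ef$n_drugs)
  truth <- character(ef$n_drugs)
  for (i in seq_len(ef$n_drugs)) {
    if (contradictory[i]) {
      pick <- sample(ef$n_lncrnas, 2L)
      rows[[i]] <- data.frame(
        drug = drugs[i], lncrna = lnc[pick],
        effect = c(verb_for(dir[pick[1L]], "therapeutic"),
                   verb_for(dir[pick[2L]], "exacerbating")),
        stringsAsFactors = FALSE)
      truth[i] <- "contradictory"
    } else {
      sign <- if (runif(1) < ef$positive_fraction) "therapeutic" else "exacerbating"
      k <- sample(seq_len(ef$max_edges), 1L)
      pick <- sample(ef$n_lncrnas, min(k, ef$n_lncrnas))
      rows[[i]] <- data.frame(
        drug = drugs[i], lncrna = lnc[pick],
        effect = verb_for(dir[pick], sign), stringsAsFactors = FALSE)
      truth[i] <- if (sign == "therapeutic") "positive" else "negative"
    }
  }
  list(effects = do.call(rbind, rows), directions = directions,
       truth = data.frame(drug = drugs, label = truth,
                          stringsAsFactors = FALSE))
}

#' Simulate a labeled descriptor matrix with planted structure
#'
#' Informative columns are Gaussian with class means `delta` pooled SDs
#' apart; nuisance noise is log-normal (heavy-tailed, like real 1D-2D
#' descriptors); constant columns take one value; correlated pairs are a
#' base noise column plus a near-duplicate (|r| > 0.95 by construction);
#' low-entropy columns concentrate more than 90% of their mass in one
#' histogram bin. An integer atom-count column (`nAtom`) is always appended.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `matrix` (a [descriptor_matrix()]), `labels` (named
#'   factor), `truth` (named lists of planted column names).
#' @export
simulate_descriptors <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "descriptors"))
  de <- spec$descriptors
  n <- de$n_pos + de$n_neg
  labels <- factor(c(rep("positive", de$n_pos), rep("negative", de$n_neg)),
                   levels = c("negative", "positive"))
  ids <- sprintf("TRAIN%03d", seq_len(n))
  names(labels) <- ids
  shift <- ifelse(labels == "positive", de$delta / 2, -de$delta / 2)

  cols <- list()
  truth <- list(informative = character(), constant = character(),
                correlated_base = character(), correlated_dup = character(),
                low_entropy = character(), noise = character())
  if (de$n_informative > 0) {
    inf <- sapply(seq_len(de$n_informative), function(j) rnorm(n) + shift)
    colnames(inf) <- sprintf("INF%03d", seq_len(de$n_informative))
    truth$informative <- colnames(inf)
    cols$inf <- inf
  }
  if (de$n_constant > 0) {
    cc <- matrix(7, n, de$n_constant,
                 dimnames = list(NULL, sprintf("CONST%03d", seq_len(de$n_constant))))
    truth$constant <- colnames(cc)
    cols$cc <- cc
  }
  if (de$n_correlated_pairs > 0) {
    base <- sapply(seq_len(de$n_correlated_pairs), function(j) rlnorm(n))
    dup <- base + matrix(rnorm(n * de$n_correlated_pairs, sd = 0.02), n) *
      rep(apply(base, 2L, sd), each = n)
    colnames(base) <- sprintf("CORB%03d", seq_len(de$n_correlated_pairs))
    colnames(dup) <- sprintf("CORD%03d", seq_len(de$n_correlated_pairs))
    truth$correlated_base <- colnames(base)
    truth$correlated_dup <- colnames(dup)
    cols$base <- base
    cols$dup <- dup
  }
  if (de$n_low_entropy > 0) {
    le <- sapply(seq_len(de$n_low_entropy), function(j) {
      v <- rep(0, n)
      k <- max(1L, floor(0.08 * n))        # < 10% of mass off the modal bin
      v[sample(n, k)] <- rnorm(k, mean = 10, sd = 1)
      v
    })
    colnames(le) <- sprintf("LOWENT%03d", seq_len(de$n_low_entropy))
    truth$low_entropy <- colnames(le)
    cols$le <- le
  }
  if (de$n_noise > 0) {
    nz <- sapply(seq_len(de$n_noise), function(j) rlnorm(n))
    colnames(nz) <- sprintf("NOISE%03d", seq_len(de$n_noise))
    truth$noise <- colnames(nz)
    if (de$missing_rate > 0) {
      miss <- matrix(runif(length(nz)) < de$missing_rate, nrow = n)
      nz[miss] <- NA
    }
    cols$nz <- nz
  }
  natom <- matrix(sample(20:80, n, replace = TRUE), ncol = 1L,
                  dimnames = list(NULL, "nAtom"))
  m <- do.call(cbind, c(unname(cols), list(natom)))
  rownames(m) <- ids
  list(matrix = descriptor_matrix(m, natom_column = "nAtom"),
       labels = labels, truth = truth)
}

#' Simulate an external screening library around a training matrix
#'
#' In-domain drugs are drawn from a Gaussian fitted to the training rows;
#' planted far-outliers are placed at a fixed Mahalanobis distance from the
#' training centroid; planted strong positives sit tightly around the
#' positive-class centroid (requires `labels`); a configured fraction of the
#' remaining drugs is given an atom count below 7 (the rest 20-80).
#' Ground-truth flags are returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param training descriptor matrix whose non-atom-count columns define the
#'   chemistry to emulate (e.g. a [drug_classifier()]'s `$training`).
#' @param labels training class labels, needed when
#'   `spec$screen$strong_fraction > 0`.
#' @return A list: `matrix` (a [descriptor_matrix()] with `nAtom`), `truth`
#'   (data frame: id, outlier, strong_positive, small).
#' @export
simulate_screen_library <- function(spec, training, labels = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), is.matrix(training))
  set.seed(stage_seed(spec$seed, "screen"))
  sc <- spec$screen
  feats <- setdiff(colnames(training),
                   c(attr(training, "natom_column"), "nAtom"))
  if (!length(feats)) stop("training matrix has no non-atom-count feature")
  Xt <- training[, feats, drop = FALSE]
  if (anyNA(Xt)) {  # moment fit only; mean-impute missing training cells
    for (j in seq_len(ncol(Xt))) {
      v <- Xt[, j]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      Xt[, j] <- v
    }
  }
  mu <- colMeans(Xt)
  S <- stats::cov(Xt) + diag(1e-8, ncol(Xt))
  n <- sc$n_screen
  ids <- sprintf("FDA%04d", seq_len(n))
  kind <- sample(c("outlier", "strong", "regular"), n, replace = TRUE,
                 prob = c(sc$outlier_fraction, sc$strong_fraction,
                          1 - sc$outlier_fraction - sc$strong_fraction))
  outlier <- kind == "outlier"
  strong <- kind == "strong"
  X <- MASS::mvrnorm(n, mu = mu, Sigma = S)
  if (any(outlier)) {
    L <- chol(S)
    for (i in which(outlier)) {
      u <- rnorm(ncol(Xt))
      u <- u / sqrt(sum(u^2))
      X[i, ] <- mu + sc$outlier_distance * drop(crossprod(L, u))
    }
  }
  if (any(strong)) {
    if (is.null(labels)) {
      stop("strong_fraction > 0 needs the training labels to locate the ",
           "positive class")
    }
    labels <- align_labels(Xt, labels)
    pos_rows <- Xt[labels == "positive", , drop = FALSE]
    mu_pos <- colMeans(pos_rows)
    S_pos <- stats::cov(pos_rows) + diag(1e-8, ncol(Xt))
    X[strong, ] <- matrix(mu_pos, sum(strong), ncol(Xt), byrow = TRUE) +
      MASS::mvrnorm(sum(strong), mu = rep(0, ncol(Xt)), Sigma = 0.25 * S_pos)
  }
  colnames(X) <- feats
  rownames(X) <- ids
  # atom-count rule must not eat the planted recovery targets
  small <- runif(n) < sc$small_fraction & !strong & !outlier
  natom <- ifelse(small, sample(1:6, n, replace = TRUE),
                  sample(20:80, n, replace = TRUE))
  m <- cbind(X, nAtom = natom)
  list(matrix = descriptor_matrix(m, natom_column = "nAtom"),
       truth = data.frame(id = ids, outlier = outlier,
                          strong_positive = strong, small = small,
                          stringsAsFactors = FALSE))
}

#' Write all tables of a synthetic study to a directory
#'
#' Materializes one full synthetic input set (edge lists, effect and
#' direction tables, training descriptor CSV with labels, screening library
#' CSV) so the pipeline can be exercised from files exactly as with real
#' exports.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_to_dir <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nets <- simulate_networks(spec)
  eff <- simulate_effect_table(spec)
  des <- simulate_descriptors(spec)
  scr <- simulate_screen_library(spec, des$matrix, des$labels)
  paths <- list(
    mrna_mirna = file.path(dir, "mrna_mirna.tsv"),
    mirna_lncrna = file.path(dir, "mirna_lncrna.tsv"),
    effects = file.path(dir, "drug_effects.tsv"),
    directions = file.path(dir, "lncrna_directions.tsv"),
    descriptors = file.path(dir, "train_descriptors.csv"),
    labels = file.path(dir, "train_labels.tsv"),
    screen = file.path(dir, "screen_descriptors.csv")
  )
  write_report_tsv(as.data.frame(nets$mrna_mirna), paths$mrna_mirna)
  write_report_tsv(as.data.frame(nets$mirna_lncrna), paths$mirna_lncrna)
  write_report_tsv(eff$effects, paths$effects)
  write_report_tsv(eff$directions, paths$directions)
  write_descriptor_csv(des$matrix, paths$descriptors)
  write_report_tsv(data.frame(drug = names(des$labels),
                              class = as.character(des$labels)),
                   paths$labels)
  write_descriptor_csv(scr$matrix, paths$screen)
  invisible(paths)
}
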