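# shared fixtures built in code

# toy 3x2 complete bipartite edge list
complete_bipartite_edges <- function(layer = "mrna_mirna") {
  make_edges(expand.grid(source = c("p1", "p2", "p3"),
                         target = c("m1", "m2"),
                         stringsAsFactors = FALSE), layer)
}

# effect records consistent with the packaged drug classes: a positive drug
# opposes each lncRNA's disease direction, a negative drug reinforces it
fixture_effects <- function() {
  tab5 <- load_fixture("table5_drug_classes")
  tab4 <- load_fixture("table4_directions")
  dirs <- stats::setNames(as.character(tab4$direction_dm), tab4$lncrna)
  rows <- lapply(seq_len(nrow(tab5)), function(i) {
    lncs <- trimws(strsplit(tab5$lncrnas[i], ",")[[1]])
    d <- dirs[lncs]
    eff <- if (tab5$class[i] == "positive") {
      ifelse(d == "up", "decrease", "increase")
    } else {
      ifelse(d == "up", "increase", "decrease")
    }
    data.frame(drug = tab5$drug[i], lncrna = lncs, effect = eff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# compact descriptor spec used throughout: 6 informative + small planted
# nuisance blocks, study-sized rows (16/24)
small_desc_spec <- function(seed, delta = 3, ...) {
  synthetic_spec(seed = seed,
                 descriptors = utils::modifyList(
                   list(delta = delta, n_constant = 5, n_correlated_pairs = 5,
                        n_low_entropy = 5, n_noise = 30),
                   list(...)))
}

# separable two-cluster matrix for classifier sanity checks
separable_matrix <- function(seed = 1, n_pos = 16, n_neg = 24, gap = 8) {
  set.seed(seed)
  n <- n_pos + n_neg
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("D%03d", seq_len(n)), paste0("f", 1:4)))
  lab <- factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                levels = c("negative", "positive"))
  names(lab) <- rownames(m)
  m[lab == "positive", ] <- m[lab == "positive", ] + gap
  list(matrix = m, labels = lab)
}
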