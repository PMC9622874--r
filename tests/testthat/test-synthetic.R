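test_that("generation is a pure function of spec and seed", {
  sp <- small_desc_spec(77)
  a <- simulate_descriptors(sp)
  b <- simulate_descriptors(sp)
  expect_identical(a, b)
  n1 <- simulate_networks(sp)
  n2 <- simulate_networks(sp)
  expect_identical(n1, n2)
  e1 <- simulate_effect_table(sp)
  e2 <- simulate_effect_table(sp)
  expect_identical(e1, e2)
  s1 <- simulate_screen_library(sp, a$matrix, a$labels)
  s2 <- simulate_screen_library(sp, a$matrix, a$labels)
  expect_identical(s1, s2)
  # a different seed changes the draw
  expect_false(identical(a$matrix,
                         simulate_descriptors(small_desc_spec(78))$matrix))
})

test_that("spec validation rejects impossible settings", {
  expect_error(synthetic_spec(network = list(n_planted_hubs = 500,
                                             n_right = 10)))
  expect_error(synthetic_spec(effects = list(contradiction_rate = 1.2)))
  expect_error(synthetic_spec(descriptors = list(n_pos = 1, n_neg = 1)))
  expect_error(synthetic_spec(screen = list(outlier_fraction = 0.8,
                                            strong_fraction = 0.4)))
})

test_that("zero background gives exact planted hub degrees", {
  sp <- synthetic_spec(seed = 4, network = list(
    n_left = 12, n_right = 30, p_background = 0, n_planted_hubs = 3,
    hub_degree = 5, n_right2 = 20, n_planted_hubs2 = 2, hub_degree2 = 2,
    p_background2 = 0.2))
  nets <- simulate_networks(sp)
  net <- build_network(nets$mrna_mirna)
  deg <- network_degrees(net, "right")
  expect_setequal(deg$node[deg$degree == 5], nets$hubs_mirna)
  expect_true(all(deg$degree %in% c(5L)))  # only hubs appear without background
  # second layer's left side are the first layer's planted hubs
  expect_true(all(nets$mirna_lncrna$source %in% nets$hubs_mirna))
})

test_that("contradiction-rate extremes behave as planted", {
  sp0 <- synthetic_spec(seed = 5, effects = list(contradiction_rate = 0))
  lab0 <- label_drugs(simulate_effect_table(sp0)$effects,
                      simulate_effect_table(sp0)$directions)
  expect_length(lab0$removed_contradictory, 0L)
  sp1 <- synthetic_spec(seed = 5, effects = list(contradiction_rate = 1))
  sim1 <- simulate_effect_table(sp1)
  lab1 <- label_drugs(sim1$effects, sim1$directions)
  expect_length(lab1$removed_contradictory, sp1$effects$n_drugs)
  expect_length(lab1$positives, 0L)
})

test_that("planted descriptor structure matches its advertised properties", {
  sim <- simulate_descriptors(small_desc_spec(23))
  m <- sim$matrix
  tr <- sim$truth
  expect_length(tr$constant, 5L)
  expect_true(all(apply(m[, tr$constant, drop = FALSE], 2,
                        function(v) length(unique(v))) == 1L))
  # correlated pairs exceed |r| > 0.95 by construction
  r <- vapply(seq_along(tr$correlated_base), function(i) {
    abs(cor(m[, tr$correlated_base[i]], m[, tr$correlated_dup[i]]))
  }, numeric(1))
  expect_true(all(r > 0.95))
  # low-entropy columns concentrate > 90% of mass in one histogram bin
  for (cl in tr$low_entropy) {
    expect_lt(shannon_entropy(m[, cl], 10), 1.5)
  }
  # informative columns separated by ~delta pooled SDs
  gap <- vapply(tr$informative, function(cl) {
    mean(m[sim$labels == "positive", cl]) - mean(m[sim$labels == "negative", cl])
  }, numeric(1))
  expect_true(all(gap > 1))
  expect_identical(attr(m, "natom_column"), "nAtom")

  # missing rate lands on noise columns only
  simna <- simulate_descriptors(small_desc_spec(24, missing_rate = 0.1))
  expect_gt(sum(is.na(simna$matrix[, simna$truth$noise])), 0)
  expect_equal(sum(is.na(simna$matrix[, simna$truth$informative])), 0)
})

test_that("screen library plants smalls, outliers and strong positives", {
  sim <- simulate_descriptors(small_desc_spec(9))
  fit <- drug_classifier(sim$matrix, sim$labels, seed = 9)
  n <- 600
  scr <- simulate_screen_library(synthetic_spec(seed = 9,
           screen = list(n_screen = n, small_fraction = 0.1)),
           fit$training, sim$labels)
  frac_small <- mean(scr$truth$small)
  expect_lt(abs(frac_small - 0.1 * (1 - 0.04 - 0.02)),
            3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(scr$matrix[scr$truth$id[scr$truth$small], "nAtom"] < 7))
  expect_true(all(scr$matrix[scr$truth$id[!scr$truth$small], "nAtom"] >= 7))
  # outliers sit far outside the training cloud in leverage terms
  h <- leverage(scr$matrix[, fit$features, drop = FALSE], fit$training)
  names(h) <- scr$truth$id
  expect_gt(min(h[scr$truth$id[scr$truth$outlier]]),
            max(h[scr$truth$id[!scr$truth$outlier & !scr$truth$strong_positive]]) * 0.5)
  expect_error(simulate_screen_library(synthetic_spec(seed = 1), fit$training),
               "labels")
})

test_that("a full synthetic study round-trips through a directory", {
  sp <- synthetic_spec(seed = 33,
                       network = list(n_right = 60, n_right2 = 40),
                       descriptors = list(n_constant = 2, n_correlated_pairs = 2,
                                          n_low_entropy = 2, n_noise = 6),
                       screen = list(n_screen = 50))
  dir <- withr::local_tempdir()
  paths <- simulate_to_dir(sp, dir)
  expect_true(all(file.exists(unlist(paths))))
  m <- read_descriptor_csv(paths$descriptors)
  expect_equal(m, simulate_descriptors(sp)$matrix, tolerance = 1e-12)
  e <- read_edge_list(paths$mrna_mirna, "mrna_mirna", header = TRUE)
  expect_equal(nrow(e), nrow(simulate_networks(sp)$mrna_mirna))
})
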