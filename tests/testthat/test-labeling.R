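test_that("effect sign follows the direction/effect rule and its symmetry", {
  expect_equal(effect_sign("up", "decrease"), "therapeutic")
  expect_equal(effect_sign("up", "increase"), "exacerbating")
  expect_equal(effect_sign("down", "increase"), "therapeutic")
  expect_equal(effect_sign("down", "decrease"), "exacerbating")
  # involution: flipping both direction and effect preserves the sign
  for (d in c("up", "down")) for (e in c("increase", "decrease")) {
    flip_d <- ifelse(d == "up", "down", "up")
    flip_e <- ifelse(e == "increase", "decrease", "increase")
    expect_equal(effect_sign(d, e), effect_sign(flip_d, flip_e))
  }
  expect_error(effect_sign("sideways", "increase"), "direction")
})

test_that("free-text verbs map through the controlled vocabulary", {
  expect_equal(normalize_effect(c("inhibits", "Overexpresses", "silences")),
               c("decrease", "increase", "decrease"))
  expect_error(normalize_effect("modulates"), "unrecognized")
})

test_that("contradictory drugs are removed; concordant multi-target drugs kept", {
  tab4 <- load_fixture("table4_directions")
  eff <- data.frame(
    drug = c("DrugA", "DrugA",      # decreases NEAT1(up), increases MALAT1(down): uniform therapeutic
             "DrugB", "DrugB",      # decreases NEAT1(up), decreases MALAT1(down): contradictory
             "DrugC",               # increases H19(up): exacerbating
             "DrugD"),              # only hits an unknown-direction lncRNA
    lncrna = c("NEAT1", "MALAT1", "NEAT1", "MALAT1", "H19", "NORAD"),
    effect = c("decrease", "increase", "decrease", "decrease", "increase",
               "increase"),
    stringsAsFactors = FALSE)
  res <- suppressWarnings(remove_contradictory(eff, tab4))
  expect_equal(res$removed_contradictory, "DrugB")
  expect_equal(res$removed_unsignable, "DrugD")
  expect_setequal(unique(res$signed$drug), c("DrugA", "DrugC"))
  expect_true(all(res$signed$sign[res$signed$drug == "DrugA"] == "therapeutic"))

  lab <- partition_drugs(res)
  expect_equal(lab$positives, "DrugA")
  expect_equal(lab$negatives, "DrugC")

  # all-uniform table: nothing removed
  eff_ok <- data.frame(drug = paste0("U", 1:5), lncrna = "NEAT1",
                       effect = "decrease")
  expect_length(remove_contradictory(eff_ok, tab4)$removed_contradictory, 0)

  # mixed-sign drug smuggled straight into partitioning is an invariant breach
  bad <- data.frame(drug = c("Z", "Z"), sign = c("therapeutic", "exacerbating"))
  expect_error(partition_drugs(bad), "mixed-sign")
})

test_that("duplicate pairs with opposite verbs are refused for curation", {
  tab4 <- load_fixture("table4_directions")
  eff <- data.frame(drug = c("D1", "D1"), lncrna = c("NEAT1", "NEAT1"),
                    effect = c("increase", "decrease"))
  expect_error(remove_contradictory(eff, tab4), "conflicting.*D1/NEAT1")
})

test_that("labeling is invariant to input row order", {
  sim <- simulate_effect_table(synthetic_spec(seed = 3, effects = list(
    n_drugs = 60, contradiction_rate = 0.2)))
  lab1 <- label_drugs(sim$effects, sim$directions)
  shuffled <- sim$effects[sample(nrow(sim$effects)), ]
  lab2 <- label_drugs(shuffled, sim$directions)
  expect_setequal(lab1$positives, lab2$positives)
  expect_setequal(lab1$negatives, lab2$negatives)
  expect_setequal(lab1$removed_contradictory, lab2$removed_contradictory)
})

test_that("labeling the packaged drug table recovers the published partition", {
  lab <- label_drugs(fixture_effects(), load_fixture("table4_directions"))
  expect_length(lab$positives, 16L)
  expect_length(lab$negatives, 24L)
  expect_length(lab$removed_contradictory, 0L)
  # canonical cases: an NEAT1+H19 raiser is exacerbating, an NEAT1
  # inhibitor / MALAT1 raiser is therapeutic
  expect_true("Panobinostat" %in% lab$negatives)
  expect_true("Adriamycin" %in% lab$positives)
  cls <- drug_classes(lab)
  expect_equal(unname(table(cls)["negative"]), 24L)
})

test_that("planted contradiction rate is recovered within binomial error", {
  n_drugs <- 200
  rho <- 0.3
  removed_frac <- vapply(1:30, function(s) {
    sim <- simulate_effect_table(synthetic_spec(seed = s, effects = list(
      n_drugs = n_drugs, contradiction_rate = rho)))
    lab <- label_drugs(sim$effects, sim$directions)
    length(lab$removed_contradictory) / n_drugs
  }, numeric(1))
  se <- sqrt(rho * (1 - rho) / (n_drugs * 30))
  expect_lt(abs(mean(removed_frac) - rho), 3 * se)
  # and the generator's truth labels agree with the pipeline's decisions
  sim <- simulate_effect_table(synthetic_spec(seed = 99, effects = list(
    n_drugs = 80, contradiction_rate = 0.25)))
  lab <- label_drugs(sim$effects, sim$directions)
  expect_setequal(lab$removed_contradictory,
                  sim$truth$drug[sim$truth$label == "contradictory"])
  expect_setequal(lab$positives, sim$truth$drug[sim$truth$label == "positive"])
})
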