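test_that("constant columns are removed, ignoring missing cells", {
  m <- cbind(flat = rep(7, 5), live = 1:5,
             flat_na = c(3, 3, NA, 3, 3))
  rownames(m) <- paste0("d", 1:5)
  res <- remove_constant(m)
  expect_setequal(res$removed, c("flat", "flat_na"))
  expect_equal(colnames(res$matrix), "live")
  expect_error(remove_constant(cbind(a = rep(1, 3))), "constant")
})

test_that("correlation pruning drops the member with the larger mean |r|", {
  # build A ~ B (r > 0.9) with A additionally tied to C, so A has the
  # larger mean absolute correlation of the offending pair
  set.seed(42)
  C <- rnorm(60)
  B <- rnorm(60)
  A <- B + 0.12 * rnorm(60) + 0.35 * C
  m <- cbind(A = A, B = B, C = C)
  rownames(m) <- paste0("d", 1:60)
  cm <- abs(cor(m))
  expect_gt(cm["A", "B"], 0.9)
  expect_gt(mean(cm[, "A"]), mean(cm[, "B"]))
  res <- prune_correlated(m, 0.9)
  expect_equal(res$removed, "A")
  expect_setequal(colnames(res$matrix), c("B", "C"))

  # duplicates: exactly one of the pair goes
  m2 <- cbind(x = 1:10 + 0.001 * rnorm(10), y = 1:10, z = rnorm(10))
  rownames(m2) <- paste0("d", 1:10)
  res2 <- prune_correlated(m2, 0.9)
  expect_length(res2$removed, 1L)
  expect_true(res2$removed %in% c("x", "y"))

  # nothing above the cutoff: nothing removed
  expect_length(prune_correlated(m2, 1)$removed, 0L)
  expect_error(prune_correlated(m2, 0), "cutoff")
})

test_that("pruning matches the reference caret heuristic on random matrices", {
  for (s in 1:10) {
    set.seed(s)
    n <- 30; p <- 12
    base <- matrix(rnorm(n * p), n, p)
    # plant a few highly correlated pairs
    base[, 1] <- base[, 2] + 0.05 * rnorm(n)
    base[, 4] <- -base[, 5] + 0.1 * rnorm(n)
    colnames(base) <- sprintf("v%02d", 1:p)
    rownames(base) <- sprintf("d%02d", 1:n)
    ours <- prune_correlated(base, 0.9)$removed
    ref <- colnames(base)[caret::findCorrelation(cor(base), cutoff = 0.9,
                                                 exact = FALSE)]
    expect_setequal(ours, ref)
  }
})

test_that("histogram entropy matches closed forms", {
  # uniform over 10 equal-width bins: ln 10
  expect_equal(shannon_entropy(rep(seq(0.5, 9.5), 4), bins = 10), log(10),
               tolerance = 1e-12)
  # two-point 50/50 split: ln 2
  expect_equal(shannon_entropy(rep(c(0, 1), 20), bins = 10), log(2),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(3.3, 10)), 0)
  ef <- entropy_filter(cbind(flatish = c(rep(0, 19), 5),
                             spread = seq(0.5, 9.5, length.out = 20)),
                       threshold = 1.5, bins = 10)
  expect_equal(ef$removed, "flatish")
  expect_lt(ef$entropies[["flatish"]], 1.5)
  expect_gte(ef$entropies[["spread"]], 1.5)
})

test_that("t-test stage keeps separated features and ignores null ones", {
  set.seed(5)
  n_pos <- 16; n_neg <- 24
  lab <- factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                levels = c("negative", "positive"))
  names(lab) <- sprintf("d%02d", 1:40)
  same <- rnorm(40)                      # identical distribution in both classes
  planted <- rnorm(40) + ifelse(lab == "positive", 1.5, -1.5)  # 3 pooled SDs
  m <- cbind(same = same, planted = planted)
  rownames(m) <- names(lab)
  res <- ttest_filter(m, lab)
  expect_equal(res$selected, "planted")
  expect_gt(res$p_values[["same"]], 0.05)

  # power at 3 pooled SDs with 16/24 is essentially 1 across draws
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    v <- rnorm(40) + ifelse(lab == "positive", 1.5, -1.5)
    t.test(v[lab == "positive"], v[lab == "negative"])$p.value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.99)

  expect_error(ttest_filter(m, factor(rep("positive", 40),
                                      levels = c("negative", "positive"))),
               "at least 2")
})

test_that("the cascade is idempotent and row-permutation invariant", {
  sim <- simulate_descriptors(small_desc_spec(21))
  cfg <- pipeline_config()
  s1 <- select_features(sim$matrix, sim$labels, cfg)
  s2 <- select_features(s1$matrix, sim$labels, cfg)
  expect_equal(s2$selected, s1$selected)
  expect_length(s2$removed_constant, 0L)
  expect_length(s2$removed_correlated, 0L)

  perm <- sample(nrow(sim$matrix))
  m_perm <- descriptor_matrix(sim$matrix[perm, , drop = FALSE], "nAtom")
  s3 <- select_features(m_perm, sim$labels[perm], cfg)
  expect_equal(s3$selected, s1$selected)
  expect_equal(s3$removed_correlated, s1$removed_correlated)

  # the five lists partition the input feature names
  parts <- c(s1$removed_constant, s1$removed_correlated,
             s1$removed_low_entropy, s1$removed_nonsignificant, s1$selected)
  expect_setequal(parts, colnames(sim$matrix))
  expect_equal(length(parts), ncol(sim$matrix))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_report(s1, f)
  rep <- read.delim(f)
  expect_equal(nrow(rep), ncol(sim$matrix))
})

test_that("planted informative features are recovered and nuisance removed", {
  sim <- simulate_descriptors(small_desc_spec(31))
  sel <- select_features(sim$matrix, sim$labels)
  tr <- sim$truth
  expect_true(all(tr$informative %in% sel$selected))
  expect_setequal(sel$removed_constant, tr$constant)
  expect_true(all(!(tr$low_entropy %in% sel$selected)))
  # every planted correlated pair is broken at the pruning stage
  broken <- tr$correlated_base %in% sel$removed_correlated |
    tr$correlated_dup %in% sel$removed_correlated
  expect_true(all(broken))
})
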