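test_that("atom-count filter keeps the boundary case", {
  m <- descriptor_matrix(cbind(d1 = c(1, 2, 3), nAtom = c(6, 7, 30)) |>
                           `rownames<-`(c("tiny", "edge", "big")),
                         natom_column = "nAtom")
  res <- natom_filter(m, mu = 7)
  expect_equal(res$removed, "tiny")       # nATOM 6 < 7 removed
  expect_true(all(c("edge", "big") %in% rownames(res$matrix)))  # nATOM 7 kept
  expect_equal(nrow(natom_filter(m[0, , drop = FALSE], 7,
                                 natom_column = "nAtom")$matrix), 0L)
  no_atom <- m[, "d1", drop = FALSE]
  attr(no_atom, "natom_column") <- NULL
  expect_error(natom_filter(no_atom), "atom-count")
})

test_that("warning leverage reproduces the 3p/n arithmetic", {
  expect_equal(round(warning_leverage(6, 2304, 3), 4), 0.0091)
  expect_equal(warning_leverage(0, 10, 3), 0.3)       # p = 1
  expect_equal(warning_leverage(5, 100, 0), 0)        # degenerate bound
  expect_error(warning_leverage(6, 0), "no compounds")
})

test_that("leverage matches explicit hat-matrix arithmetic", {
  # 1-column basis (1, 2)': x'X = 5, so h(x = 1) = 1/5
  X <- cbind(a = c(1, 2))
  expect_equal(leverage(c(a = 1), X), 0.2)
  # orthonormal columns: h is the squared norm of the query row
  Q <- qr.Q(qr(matrix(rnorm(15), 5, 3)))
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(leverage(Q, Q), rowSums(Q^2), tolerance = 1e-12)
  # brute-force oracle: diag of X (X'X)^-1 X' and its trace
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("c", 1:3)))
    H <- X %*% solve(t(X) %*% X) %*% t(X)
    h <- leverage(X, X)
    expect_equal(h, diag(H), tolerance = 1e-10)
    expect_equal(sum(h), 3, tolerance = 1e-10)
    expect_true(all(h >= 0 & h <= 1 + 1e-12))
  }
  expect_error(leverage(c(a = 1, b = 2), cbind(a = 1:3)), "differ")
  # rank-deficient basis falls back to the pseudo-inverse with a warning
  Xr <- cbind(u = 1:4, v = 2 * (1:4))
  expect_warning(h <- leverage(Xr, Xr), "pseudo-inverse")
  expect_equal(sum(h), 1, tolerance = 1e-8)  # trace equals the rank
})

test_that("one-class SVM keeps the centroid and rejects far points", {
  set.seed(8)
  train <- matrix(rnorm(40 * 5), 40, 5,
                  dimnames = list(sprintf("t%02d", 1:40), paste0("f", 1:5)))
  centroid <- matrix(colMeans(train), 1, dimnames = list("center", paste0("f", 1:5)))
  far <- centroid + 100 * apply(train, 2, sd)
  rownames(far) <- "far"
  res <- ocsvm_filter(train, rbind(centroid, far))
  expect_true("center" %in% res$retained)
  expect_true("far" %in% res$removed)
  # nu bounds the training rejection rate (loosely, at n = 40)
  res_tr <- ocsvm_filter(train, train, nu = 0.1)
  expect_lt(length(res_tr$removed) / nrow(train), 0.35)
  # empty screen set
  res0 <- ocsvm_filter(train, train[0, , drop = FALSE])
  expect_length(res0$retained, 0L)
  degenerate <- cbind(train[, 1:4], flat = 1)
  expect_error(ocsvm_filter(degenerate, degenerate), "zero-variance")
})

test_that("candidate ranking applies the probability threshold and ordering", {
  sep <- separable_matrix(6)
  fit <- drug_classifier(sep$matrix, sep$labels, select = FALSE,
                         n_trees = 100, seed = 6)
  # training-like points: probability ~1 for their own class
  cand <- rank_candidates(fit, sep$matrix, threshold = 0.95)
  expect_true(all(cand$probability >= 0.95))
  expect_true(all(diff(cand$probability[cand$predicted_label == "positive"]) <= 0))
  # a 50/50 blend of the two clusters never reaches 0.95
  blend <- (sep$matrix[1, , drop = FALSE] + sep$matrix[40, , drop = FALSE]) / 2
  rownames(blend) <- "between"
  pr <- predict(fit, blend)
  if (max(pr) < 0.95) {
    expect_equal(nrow(rank_candidates(fit, blend, 0.95)), 0L)
  }
  # threshold 1: only unanimous drugs survive
  cand1 <- rank_candidates(fit, sep$matrix, threshold = 1)
  expect_true(all(cand1$probability == 1))
  expect_equal(nrow(rank_candidates(fit, sep$matrix[0, , drop = FALSE])), 0L)
  expect_error(rank_candidates(fit, sep$matrix, threshold = 0.4), "threshold")
})

test_that("screening stages reconcile and tightening filters shrinks retention", {
  sp <- small_desc_spec(17)
  sim <- simulate_descriptors(sp)
  fit <- drug_classifier(sim$matrix, sim$labels, seed = 17)
  scr <- simulate_screen_library(synthetic_spec(seed = 17,
           screen = list(n_screen = 400)), fit$training, sim$labels)
  rep <- screen_library(fit, scr$matrix)
  expect_equal(length(rep$removed_small) + length(rep$removed_missing) +
                 length(rep$removed_high_leverage) + length(rep$removed_ocsvm) +
                 length(rep$retained), rep$n_input)
  # removal sets are disjoint
  ids <- c(rep$removed_small, rep$removed_missing, rep$removed_high_leverage,
           rep$removed_ocsvm, rep$retained)
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(rep$leverages[rep$removed_high_leverage] > rep$h_star))

  # monotone attrition: larger mu, higher threshold never grow the output
  cfg_tight <- pipeline_config(natom_min = 20, probability_threshold = 0.99)
  rep_tight <- screen_library(fit, scr$matrix, cfg_tight)
  expect_lte(length(rep_tight$retained), length(rep$retained))
  expect_lte(nrow(rep_tight$candidates), nrow(rep$candidates))

  # training-basis convention is available and reported
  rep_tr <- screen_library(fit, scr$matrix, pipeline_config(ad_basis = "training"))
  expect_equal(rep_tr$ad_basis, "training")
  expect_equal(rep_tr$h_star,
               3 * (length(fit$features) + 1) / nrow(fit$training))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_screening_report(rep, f)
  expect_equal(nrow(read.delim(f)), rep$n_input)
})
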