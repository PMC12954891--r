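test_that("rebalancing reaches exact class parity and flags synthetic rows", {
  withr::with_seed(1, {
    x <- matrix(rnorm(570 * 4), 570, 4)
    colnames(x) <- paste0("f", 1:4)
    y <- rep(c("zero", "low", "positive"), times = c(118, 267, 185))
  })
  rb <- rebalance(x, y, seed = 2)
  expect_true(all(table(rb$labels) == 267))
  expect_equal(sum(rb$synthetic), 267 * 3 - 570)
  # synthetic rows lie between real same-class rows (convex interpolation)
  syn <- rb$matrix[rb$synthetic & rb$labels == "zero", , drop = FALSE]
  orig <- x[y == "zero", ]
  expect_true(all(syn >= matrix(apply(orig, 2, min), nrow(syn), 4, byrow = TRUE) - 1e-9))
  expect_true(all(syn <= matrix(apply(orig, 2, max), nrow(syn), 4, byrow = TRUE) + 1e-9))
  # already balanced input: unchanged counts, no synthetic rows
  yb <- rep(c("zero", "low", "positive"), each = 30)
  xb <- matrix(rnorm(90 * 4), 90, 4)
  rb2 <- rebalance(xb, yb, seed = 3)
  expect_true(all(table(rb2$labels) == 30))
  expect_false(any(rb2$synthetic))
  # determinism
  rb3 <- rebalance(x, y, seed = 2)
  expect_identical(rb$matrix, rb3$matrix)
})

test_that("a class smaller than the neighbor count lowers k with a warning", {
  x <- matrix(rnorm(11 * 3), 11, 3)
  y <- c(rep("zero", 3), rep("low", 4), rep("positive", 4))
  expect_warning(rb <- rebalance(x, y, seed = 1, k_neighbors = 5), "lowered")
  expect_true(all(table(rb$labels) == 4))
})

test_that("AUC equals exhaustive Mann-Whitney pair enumeration, ties at 1/2", {
  # hand-made 12 samples with ties
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
             FALSE, TRUE)
  expect_equal(auc_mann_whitney(scores, truth), auc_brute(scores, truth),
               tolerance = 1e-15)
  withr::with_seed(4, {
    for (i in 1:5) {
      s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
      t <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
      if (any(t) && any(!t)) {
        expect_identical(auc_mann_whitney(s, t), auc_brute(s, t))
      }
    }
  })
  # perfect separation
  expect_equal(auc_mann_whitney(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("F1 reproduces the published precision/recall arithmetic", {
  # printed per-class rows: (P, R) -> F1
  expect_equal(round(f1_from_pr(0.620, 0.746), 3), 0.677)
  expect_equal(round(f1_from_pr(0.692, 0.751), 3), 0.720)
  expect_equal(round(f1_from_pr(0.820, 0.702), 3), 0.756)
  expect_equal(round(f1_from_pr(0.672, 0.672), 3), 0.672)
  # harmonic-mean identity P = R = x -> F1 = x
  for (x in c(0.1, 0.5, 0.9)) expect_equal(f1_from_pr(x, x), x)
  expect_equal(f1_from_pr(0, 0), 0)
})

test_that("grid search trains, predicts coherently, and separates signal from null", {
  sm <- make_signal_matrix(n = 120, p = 12, signal_cols = 1:3, effect = 2,
                           seed = 5)
  single <- data.frame(n_trees = 100, max_depth = 3, learning_rate = 0.1,
                       row_subsample = 0.8, col_subsample = 0.8)
  clf <- grid_search_train(sm$x, sm$y, grid = single, n_folds = 3, seed = 6)
  expect_equal(clf$best_params$n_trees, 100)  # degenerate grid: that point
  expect_gte(clf$cv_macro_auc, 0.8)
  expect_false(clf$validation_synthetic)
  pr <- predict_proba(clf, sm$x)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  expect_identical(pr[1, ], pr[1, ])
  # duplicate rows produce identical outputs
  x2 <- sm$x[c(1, 1, 2), ]
  p2 <- predict_proba(clf, x2)
  expect_identical(p2[1, ], p2[2, ])
  # missing columns are a named error
  expect_error(predict_proba(clf, sm$x[, -1]), colnames(sm$x)[1])
  # permuted labels: chance-level CV AUC
  withr::with_seed(7, ynull <- sample(sm$y))
  clf0 <- grid_search_train(sm$x, ynull, grid = single, n_folds = 3, seed = 8)
  expect_gte(clf0$cv_macro_auc, 0.4)
  expect_lte(clf0$cv_macro_auc, 0.6)
  # stochastic grid points retrain identically under the same seed
  clf2 <- grid_search_train(sm$x, sm$y, grid = single, n_folds = 3, seed = 6)
  expect_identical(predict_proba(clf2, sm$x), pr)
})

test_that("evaluation reports are internally consistent", {
  sm <- make_signal_matrix(n = 90, p = 10, signal_cols = 1:3, effect = 2.5,
                           seed = 9)
  single <- data.frame(n_trees = 50, max_depth = 3, learning_rate = 0.3,
                       row_subsample = 1, col_subsample = 1)
  clf <- grid_search_train(sm$x, sm$y, grid = single, n_folds = 3, seed = 10)
  pr <- predict_proba(clf, sm$x)
  ev <- evaluate_ovr(pr, sm$y, n_boot = 200, seed = 11, cohort = "resub")
  expect_equal(sum(ev$confusion), 90)
  expect_equal(unname(rowSums(ev$confusion)), unname(as.integer(table(factor(sm$y,
    levels = c("zero", "low", "positive"))))))
  for (cl in names(ev$per_class)) {
    pc <- ev$per_class[[cl]]
    expect_equal(pc$f1, f1_from_pr(pc$precision, pc$sensitivity), tolerance = 1e-12)
    expect_true(all(c(pc$accuracy, pc$sensitivity, pc$specificity,
                      pc$precision, pc$f1) >= 0))
    expect_true(all(c(pc$accuracy, pc$sensitivity, pc$specificity,
                      pc$precision, pc$f1) <= 1))
    expect_true(pc$ci[1] <= pc$auc + 1e-9 && pc$auc <= pc$ci[2] + 1e-9)
    # AUC equals the brute-force pairwise oracle on the same scores
    truth <- sm$y == cl
    expect_equal(pc$auc, auc_brute(pr[, cl], truth), tolerance = 1e-12)
  }
  # perfectly separating scores give unit AUC
  ideal <- matrix(0, 90, 3, dimnames = list(NULL, c("zero", "low", "positive")))
  ideal[cbind(seq_len(90), as.integer(factor(sm$y, c("zero", "low", "positive"))))] <- 1
  ev2 <- evaluate_ovr(ideal, sm$y, n_boot = 50, seed = 12)
  for (cl in names(ev2$per_class)) expect_equal(ev2$per_class[[cl]]$auc, 1)
})

test_that("validation folds never contain synthetic rows", {
  # structural audit: rebalance only ever touches the training fold, and its
  # synthetic flags never appear on validation rows
  withr::with_seed(13, {
    x <- matrix(rnorm(60 * 5), 60, 5)
    colnames(x) <- paste0("f", 1:5)
    y <- rep(c("zero", "low", "positive"), times = c(10, 30, 20))
    rownames(x) <- sprintf("R%02d", 1:60)
  })
  foldid <- habitomics:::stratified_folds(factor(y, c("zero", "low", "positive")),
                                          3, 1)
  for (f in 1:3) {
    rb <- rebalance(x[foldid != f, ], y[foldid != f], seed = f)
    va <- rownames(x)[foldid == f]
    syn_rows <- rownames(rb$matrix)[rb$synthetic]
    expect_length(intersect(va, syn_rows), 0)
    # and every class is present in both parts
    expect_length(unique(y[foldid == f]), 3)
  }
})
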