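make_trained <- function(n = 80, p = 6, effect = 2, seed = 21,
                         pars = data.frame(n_trees = 60, max_depth = 3,
                                           learning_rate = 0.1,
                                           row_subsample = 0.8,
                                           col_subsample = 0.8)) {
  sm <- make_signal_matrix(n = n, p = p, signal_cols = 1:3, effect = effect,
                           seed = seed)
  clf <- grid_search_train(sm$x, sm$y, grid = pars, n_folds = 3, seed = seed + 1)
  list(sm = sm, clf = clf)
}

test_that("Shapley additivity holds for every sample and class to 1e-6", {
  tt <- make_trained()
  ex <- compute_shap(tt$clf, tt$sm$x)
  recon <- apply(ex$phi, c(1, 3), sum) +
    matrix(ex$base_values, nrow(tt$sm$x), 3, byrow = TRUE)
  expect_lt(max(abs(recon - ex$margins)), 1e-6)
  # margins agree with the booster's own margin predictions
  marg_ref <- predict(tt$clf$booster, xgboost::xgb.DMatrix(tt$sm$x),
                      outputmargin = TRUE)
  expect_lt(max(abs(ex$margins - marg_ref)), 1e-4)
})

test_that("attributions agree with the boosting library's contribution predictor", {
  tt <- make_trained(n = 50, p = 5)
  ex <- compute_shap(tt$clf, tt$sm$x)
  pc <- predict(tt$clf$booster, xgboost::xgb.DMatrix(tt$sm$x), predcontrib = TRUE)
  phi_ref <- aperm(pc[, , seq_len(5), drop = FALSE], c(1, 3, 2))
  expect_lt(max(abs(ex$phi - phi_ref)), 1e-5)
})

test_that("a single-split tree puts all attribution on its feature, matching brute force", {
  # one deep-enough signal so a depth-1, single-tree model splits once
  withr::with_seed(31, {
    x <- cbind(f1 = c(rnorm(30, -2), rnorm(30, 2)), f2 = rnorm(60))
    y <- rep(c(0, 1), each = 30)
  })
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logitraw", max_depth = 1, eta = 1,
                  nthread = 1, seed = 1),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = 1)
  parsed <- habitomics:::parse_booster_trees(bst)
  tr <- parsed$trees[[1]]
  expect_identical(tr$fidx[1], 1L)  # split on f1
  p <- ncol(x)
  phi1 <- habitomics:::tree_shap_one(tr, habitomics:::as_float32(x[1, ]), p)
  # brute-force Shapley with the cover-weighted tree as value function and
  # the path-dependent expectation as background behavior: for a single
  # split both reduce to f(x) - E[f]
  fx <- habitomics:::tree_value(tr, habitomics:::as_float32(x[1, ]))
  ev <- habitomics:::tree_expected_value(tr)
  expect_equal(phi1[1], fx - ev, tolerance = 1e-12)
  expect_identical(phi1[2], 0)
  # and the generic brute-force oracle agrees when the empirical background
  # reproduces the training cover weights
  f <- function(z) habitomics:::tree_value(tr, z)
  bg <- matrix(habitomics:::as_float32(x), nrow(x), ncol(x))
  phi_bf <- shapley_brute_force(f, habitomics:::as_float32(x[1, ]), bg)
  # agreement is limited only by the float32 storage of covers/leaf values
  expect_equal(phi1[1], phi_bf[1], tolerance = 1e-6)
  expect_equal(phi_bf[2], 0)
})

test_that("duplicated features used symmetrically receive equal attribution", {
  # hand-built symmetric function of two identical columns
  f <- function(z) as.numeric(z[1] > 0) + as.numeric(z[2] > 0)
  withr::with_seed(5, bg <- matrix(rnorm(200), 100, 2))
  bg[, 2] <- bg[, 1]  # exactly duplicated columns
  x <- c(1, 1)
  phi <- shapley_brute_force(f, x, bg)
  expect_equal(phi[1], phi[2], tolerance = 1e-12)
  expect_equal(sum(phi) + attr(phi, "base"), f(x), tolerance = 1e-12)
})

test_that("features the ensemble never splits on have zero attribution", {
  tt <- make_trained(n = 60, p = 8)
  ex <- compute_shap(tt$clf, tt$sm$x)
  used <- unique(unlist(lapply(habitomics:::parse_booster_trees(tt$clf$booster)$trees,
                               function(tr) tr$fidx[!tr$leaf])))
  unused <- setdiff(seq_len(8), used)
  if (length(unused) > 0) {
    expect_true(all(ex$phi[, unused, ] == 0))
  }
  # constant model: constant inputs leave nothing to split on, so every
  # tree is a single leaf and all attributions are zero
  xconst <- matrix(0, nrow(tt$sm$x), ncol(tt$sm$x),
                   dimnames = dimnames(tt$sm$x))
  const <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3, max_depth = 3,
                  eta = 0.1, nthread = 1, seed = 1),
    data = xgboost::xgb.DMatrix(xconst,
                                label = as.integer(factor(tt$sm$y,
                                  c("zero", "low", "positive"))) - 1L),
    nrounds = 3)
  fake <- tt$clf
  fake$booster <- const
  ex0 <- compute_shap(fake, tt$sm$x)
  expect_true(all(abs(ex0$phi) < 1e-12))
})

test_that("global summary ranks by mean |phi| and is sample-order invariant", {
  tt <- make_trained()
  ex <- compute_shap(tt$clf, tt$sm$x)
  gs <- global_summary(ex, "zero", top_n = 4)
  expect_equal(nrow(gs), 4)
  expect_true(all(diff(gs$mean_abs_shap) <= 0))
  # a planted-signal feature ranks at the top
  expect_true(any(grepl("_F[123]_", gs$feature[1:3])))
  perm <- sample(nrow(tt$sm$x))
  ex2 <- compute_shap(tt$clf, tt$sm$x[perm, ])
  gs2 <- global_summary(ex2, "zero", top_n = 4)
  expect_identical(gs$feature, gs2$feature)
  expect_equal(gs$mean_abs_shap, gs2$mean_abs_shap, tolerance = 1e-12)
  # top_n beyond the feature count returns the full list
  expect_equal(nrow(global_summary(ex, "zero", top_n = 100)), 6)
})

test_that("waterfalls are additive and consistent with predicted probabilities", {
  tt <- make_trained()
  ex <- compute_shap(tt$clf, tt$sm$x)
  pr <- predict_proba(tt$clf, tt$sm$x)
  for (i in c(1, 17)) {
    for (cl in c("zero", "low", "positive")) {
      wf <- waterfall(ex, i, cl)
      expect_equal(wf$end_margin, wf$base_margin + sum(wf$steps$phi),
                   tolerance = 1e-9)
      expect_equal(utils::tail(wf$steps$cumulative, 1), wf$end_margin,
                   tolerance = 1e-9)
      expect_gt(wf$prob_start, 0); expect_lt(wf$prob_start, 1)
      expect_equal(wf$prob_end, unname(pr[i, cl]), tolerance = 1e-6)
      expect_equal(wf$steps$feature[1],
                   names(which.max(abs(ex$phi[i, , cl]))))
    }
  }
  expect_error(waterfall(ex, 1e4, "zero"), "invalid")
})
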