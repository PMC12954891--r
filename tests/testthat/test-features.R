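test_that("first-order moments match hand computation on a 3x3x3 region", {
  withr::with_seed(4, vals <- round(rnorm(27, 50, 10), 3))
  img <- array(vals, c(3, 3, 3))
  mask <- array(1L, c(3, 3, 3))
  fv <- extract_region_features(img, mask, c(1, 1, 1),
                                radiomics_config(bin_width = 5, log_sigmas = numeric(0),
                                                 wavelet = FALSE))
  # hand computation: population moments written out explicitly
  n <- 27
  mu <- sum(vals) / n
  m2 <- sum((vals - mu)^2) / n
  m3 <- sum((vals - mu)^3) / n
  expect_equal(unname(fv["original_firstorder_Mean"]), mu, tolerance = 1e-9)
  expect_equal(unname(fv["original_firstorder_Variance"]), m2, tolerance = 1e-9)
  expect_equal(unname(fv["original_firstorder_Skewness"]), m3 / m2^1.5,
               tolerance = 1e-9)
  expect_equal(unname(fv["original_firstorder_Energy"]), sum(vals^2),
               tolerance = 1e-9)
})

test_that("constant regions have zero variance and zero entropy", {
  img <- array(3.5, c(4, 4, 4))
  mask <- array(1L, c(4, 4, 4))
  fv <- extract_region_features(img, mask, c(1, 1, 1),
                                radiomics_config(log_sigmas = numeric(0),
                                                 wavelet = FALSE))
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
  expect_equal(unname(fv["original_firstorder_Entropy"]), 0)
  expect_equal(unname(fv["original_firstorder_Uniformity"]), 1)
  expect_equal(unname(fv["original_glcm_Contrast"]), 0)
})

test_that("a digital ball has near-unit sphericity", {
  b <- digital_ball(10)
  img <- array(1, dim(b))
  fv <- extract_region_features(img, b, c(1, 1, 1),
                                radiomics_config(log_sigmas = numeric(0),
                                                 wavelet = FALSE))
  expect_gte(unname(fv["original_shape_Sphericity"]), 0.95)
  expect_lte(unname(fv["original_shape_Sphericity"]), 1.0)
  expect_equal(unname(fv["original_shape_VoxelVolume"]), sum(b))
  # elongation/flatness of a sphere ~ 1
  expect_gt(unname(fv["original_shape_Flatness"]), 0.95)
  # max diameter close to 2r
  expect_equal(unname(fv["original_shape_Maximum3DDiameter"]), 20,
               tolerance = 0.1)
})

test_that("tiny regions are treated as missing and mismatched shapes error", {
  img <- array(rnorm(64), c(4, 4, 4))
  small <- array(0L, c(4, 4, 4)); small[1:2, 1, 1] <- 1L
  expect_null(extract_region_features(img, small, c(1, 1, 1)))
  expect_error(extract_region_features(img, array(1L, c(5, 4, 4)), c(1, 1, 1)),
               "mismatch")
})

fixture_cohort_features <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    studies <- lapply(1:3, function(i) make_tiny_study(k = 2, noise_sd = 2,
                                                       seed = 100 + i))
    maps <- lapply(studies, function(s)
      compute_perfusion_maps(s$phase_pre, s$phase_early, s$phase_delayed, s$tumor_mask))
    pool <- pool_voxel_vectors(studies, maps, 800, seed = 1)
    mod <- fit_habitat_model(pool, k_min = 2, k_max = 3, seed = 2)
    masks <- mapply(assign_habitats, studies, maps,
                    MoreArgs = list(model = mod), SIMPLIFY = FALSE)
    cfg <- radiomics_config(log_sigmas = 2, wavelet = FALSE)
    cache <<- list(studies = studies, maps = maps, model = mod, masks = masks,
                   cfg = cfg,
                   fm = build_feature_matrix(studies, masks, mod, cfg))
    cache
  }
})

test_that("feature-matrix columns equal k times the per-region count", {
  fx <- fixture_cohort_features()
  fm <- fx$fm
  per <- attr(fm, "per_region_count")
  expect_equal(ncol(fm), expected_feature_columns(fx$model$k, per))
  expect_equal(nrow(fm), 3)
  parsed <- parse_feature_name(colnames(fm))
  expect_true(all(parsed$habitat %in% seq_len(fx$model$k)))
  expect_true(all(parsed$class %in% c("shape", "firstorder", "glcm", "glrlm",
                                      "glszm", "gldm", "ngtdm")))
  expect_false(anyDuplicated(colnames(fm)) > 0)
})

test_that("absent habitats yield NA for the habitat's full column block", {
  fx <- fixture_cohort_features()
  masks <- fx$masks
  # collapse habitat 2 into habitat 1 for patient 2
  m2 <- masks[[2]]
  m2$labels[m2$labels == 2L] <- 1L
  m2$counts <- tabulate(m2$labels[m2$labels > 0], fx$model$k)
  masks2 <- masks; masks2[[2]] <- m2
  fm <- build_feature_matrix(fx$studies, masks2, fx$model, fx$cfg)
  hab2 <- grepl("_Habitat2$", colnames(fm))
  expect_true(all(is.na(fm[2, hab2])))
  expect_false(anyNA(fm[2, !hab2]))
  expect_false(anyNA(fm[1, ]))
})

test_that("extraction is deterministic and patient-order invariant", {
  strip <- function(m) {
    m <- unclass(m)
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    m
  }
  fx <- fixture_cohort_features()
  fm2 <- build_feature_matrix(fx$studies, fx$masks, fx$model, fx$cfg)
  expect_identical(strip(fx$fm), strip(fm2))
  ord <- c(3, 1, 2)
  fm3 <- build_feature_matrix(fx$studies[ord], fx$masks[ord], fx$model, fx$cfg)
  expect_identical(strip(fm3), strip(fx$fm)[ord, ])
})

test_that("KNN imputation honors its contracts", {
  withr::with_seed(5, {
    m <- matrix(rnorm(60), 10, 6)
    rownames(m) <- sprintf("R%02d", 1:10)
    colnames(m) <- sprintf("C%d", 1:6)
  })
  # no missing entries: identity
  expect_identical(impute_missing(m, 1:6), m)
  # one missing cell, neighbor pool = all training rows -> training col mean
  m2 <- m; m2[8, 3] <- NA
  out <- impute_missing(m2, 1:6, n_neighbors = 6)
  expect_equal(out[8, 3], mean(m[1:6, 3]))
  # column missing in every training row is a named error
  m3 <- m; m3[1:6, 2] <- NA
  expect_error(impute_missing(m3, 1:6), "C2")
})

test_that("imputed habitat blocks correlate with the true extracted values", {
  fx <- fixture_cohort_features()
  fm <- unclass(fx$fm)
  hab1 <- grepl("_Habitat1$", colnames(fm))
  truth <- fm[3, hab1]
  holed <- fm
  holed[3, hab1] <- NA
  out <- impute_missing(holed, 1:3, n_neighbors = 2)
  expect_false(anyNA(out))
  keep <- is.finite(truth) & apply(out[, hab1, drop = FALSE], 2, var) >= 0
  expect_gt(cor(out[3, hab1][keep], truth[keep]), 0)
})

test_that("z-scoring uses training statistics only", {
  m <- matrix(c(2, 4, 6, 8), 4, 1, dimnames = list(NULL, "f"))
  st <- compute_train_stats(m, 1:3)
  z <- zscore_transform(m, st)
  # training rows: mean 0, population sd 1
  expect_equal(mean(z[1:3, 1]), 0, tolerance = 1e-9)
  expect_equal(habitomics:::pop_sd(z[1:3, 1]), 1, tolerance = 1e-9)
  # test row transformed with TRAINING stats: (8 - 4) / 1.633 = 2.449
  expect_equal(unname(z[4, 1]), 2.4494897, tolerance = 1e-6)
  # leakage audit: recomputing stats on all rows gives different values
  st_all <- compute_train_stats(m, 1:4)
  expect_false(isTRUE(all.equal(st$mean, st_all$mean)))
  # zero-sd columns map to zero and are flagged
  m2 <- cbind(m, g = rep(5, 4))
  st2 <- compute_train_stats(m2, 1:3)
  z2 <- zscore_transform(m2, st2)
  expect_true(all(z2[, "g"] == 0))
  expect_identical(attr(z2, "degenerate"), "g")
})
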