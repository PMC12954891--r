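test_that("voxel pooling respects the per-patient cap and provenance", {
  studies <- lapply(c(41, 42, 43), function(s) make_tiny_study(k = 2, noise_sd = 2, seed = s))
  maps <- lapply(studies, function(s)
    compute_perfusion_maps(s$phase_pre, s$phase_early, s$phase_delayed, s$tumor_mask))
  avail <- vapply(maps, function(m) sum(m$valid_mask), integer(1))
  cap <- 200
  pool <- pool_voxel_vectors(studies, maps, cap_per_patient = cap, seed = 5)
  expect_equal(nrow(pool$vectors), sum(pmin(avail, cap)))
  expect_equal(as.vector(table(pool$patient_id)), pmin(avail, cap))
  # below-cap patients keep every valid voxel
  pool_all <- pool_voxel_vectors(studies, maps, cap_per_patient = 1e6, seed = 5)
  expect_equal(nrow(pool_all$vectors), sum(avail))
  pool2 <- pool_voxel_vectors(studies, maps, cap_per_patient = cap, seed = 5)
  expect_identical(pool$vectors, pool2$vectors)
})

test_that("silhouette matches the hand-worked two-cluster example", {
  x <- rbind(c(0, 0, 0), c(0, 0, 1), c(10, 0, 0), c(10, 0, 1))
  lab <- c(1, 1, 2, 2)
  # by hand: a = 1 for every point; b = (10 + sqrt(101)) / 2
  b <- (10 + sqrt(101)) / 2
  expected <- (b - 1) / b
  expect_equal(silhouette_score(x, lab), expected, tolerance = 1e-12)
  expect_gt(expected, 0.89)
  expect_error(silhouette_score(x, rep(1, 4)), "single")
})

test_that("silhouette and Davies-Bouldin match brute-force oracles to 1e-12", {
  withr::with_seed(7, {
    x <- matrix(rnorm(150), 50, 3)
    lab <- sample(1:3, 50, replace = TRUE)
  })
  expect_equal(silhouette_score(x, lab), silhouette_brute(x, lab),
               tolerance = 1e-12)
  expect_equal(davies_bouldin_index(x, lab), db_brute(x, lab),
               tolerance = 1e-12)
  # two clusters from one distribution: silhouette near zero
  withr::with_seed(8, {
    y <- matrix(rnorm(300), 100, 3)
    lab2 <- rep(1:2, 50)
  })
  expect_lt(abs(silhouette_score(y, lab2)), 0.1)
})

test_that("Davies-Bouldin matches the two-cluster closed form and flags coincident centroids", {
  # tight symmetric clusters: spread 0.1, separation 10 -> (s1+s2)/d = 0.02
  x <- rbind(c(-0.1, 0, 0), c(0.1, 0, 0), c(9.9, 0, 0), c(10.1, 0, 0))
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin_index(x, lab), 0.02, tolerance = 1e-12)
  # coincident centroids -> infinite index
  xx <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0), c(1, -1, 0))
  expect_equal(davies_bouldin_index(xx, c(1, 1, 2, 2)), Inf)
})

test_that("the habitat model recovers planted k and labels", {
  for (k in c(2, 4)) {
    studies <- lapply(1:3, function(i) make_tiny_study(k = k, noise_sd = 2,
                                                       seed = 50 + 10 * k + i))
    maps <- lapply(studies, function(s)
      compute_perfusion_maps(s$phase_pre, s$phase_early, s$phase_delayed, s$tumor_mask))
    pool <- pool_voxel_vectors(studies, maps, cap_per_patient = 800, seed = 2)
    mod <- fit_habitat_model(pool, seed = 3, metric_cap = 2000)
    expect_identical(mod$k, as.integer(k))
    expect_true(all(diff(mod$centroids[, "wash_in"]) > 0))
    mod2 <- fit_habitat_model(pool, seed = 3, metric_cap = 2000)
    expect_equal(mod$centroids, mod2$centroids)
    expect_equal(mod$selection_table, mod2$selection_table)
    expect_equal(nrow(mod$selection_table), 9)  # k = 2..10 all scored
  }
})

test_that("assignment reproduces planted truth on a noise-free phantom", {
  skip_if_not_installed("mclust")
  st <- make_tiny_study(k = 3, noise_sd = 0, seed = 77)
  pm <- compute_perfusion_maps(st$phase_pre, st$phase_early, st$phase_delayed,
                               st$tumor_mask, epsilon = 1e-9)
  pool <- pool_voxel_vectors(list(st), list(pm), cap_per_patient = 3000, seed = 1)
  mod <- fit_habitat_model(pool, seed = 2, metric_cap = 2000)
  expect_identical(mod$k, 3L)
  hm <- assign_habitats(st, pm, mod)
  v <- which(st$tumor_mask != 0)
  expect_equal(mclust::adjustedRandIndex(hm$labels[v], st$truth_habitats[v]), 1)
  # partition invariant
  expect_equal(sum(hm$counts), length(v))
  expect_true(all(hm$labels[v] >= 1))
  expect_true(all(hm$labels[st$tumor_mask == 0] == 0))
})

test_that("a voxel exactly at a centroid takes that centroid's label", {
  st <- make_tiny_study(k = 2, noise_sd = 1, seed = 91)
  pm <- compute_perfusion_maps(st$phase_pre, st$phase_early, st$phase_delayed,
                               st$tumor_mask)
  pool <- pool_voxel_vectors(list(st), list(pm), cap_per_patient = 2000, seed = 1)
  mod <- fit_habitat_model(pool, k_min = 2, k_max = 3, seed = 2)
  # overwrite one valid voxel's perfusion values with centroid h's values
  v <- which(pm$valid_mask == 1)[1]
  for (h in seq_len(mod$k)) {
    pm$wash_in[v] <- mod$centroids[h, 1]
    pm$wash_out[v] <- mod$centroids[h, 2]
    pm$wash_out_ratio[v] <- mod$centroids[h, 3]
    hm <- assign_habitats(st, pm, mod)
    expect_identical(hm$labels[v], h)
  }
})

test_that("refitting with a different pooling seed yields concordant assignments", {
  skip_if_not_installed("mclust")
  studies <- lapply(1:3, function(i) make_tiny_study(k = 3, noise_sd = 2, seed = 60 + i))
  maps <- lapply(studies, function(s)
    compute_perfusion_maps(s$phase_pre, s$phase_early, s$phase_delayed, s$tumor_mask))
  m1 <- fit_habitat_model(pool_voxel_vectors(studies, maps, 800, seed = 1),
                          seed = 5, metric_cap = 2000)
  m2 <- fit_habitat_model(pool_voxel_vectors(studies, maps, 800, seed = 99),
                          seed = 5, metric_cap = 2000)
  expect_identical(m1$k, m2$k)
  h1 <- assign_habitats(studies[[1]], maps[[1]], m1)
  h2 <- assign_habitats(studies[[1]], maps[[1]], m2)
  v <- which(studies[[1]]$tumor_mask != 0)
  # canonical ordering makes labels directly comparable across refits
  expect_gte(mean(h1$labels[v] == h2$labels[v]), 0.9)
})
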