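# Population-level perfusion habitat discovery.
#
# Voxel perfusion vectors (WI, WO, WOR) are pooled across the training
# cohort (capped per patient), standardized per dimension, and clustered by
# k-means for k = 2..10. The cluster count is selected by the silhouette
# coefficient, with the Davies-Bouldin index reported alongside (a warning
# is raised if the two criteria disagree). One shared model labels every
# patient so habitat identity is comparable cohort-wide.

#' Pool valid voxel perfusion vectors across studies
#'
#' @param studies List of `dce_study`.
#' @param maps List of `perfusion_maps`, aligned with `studies`.
#' @param cap_per_patient Maximum voxels sampled (uniformly, without
#'   replacement) per patient. Default 2000.
#' @param seed RNG seed for the per-patient subsampling.
#' @return A `voxel_vector_set`: `vectors` (n x 3 matrix, columns
#'   WI/WO/WOR), `patient_id` and `voxel_index` provenance, and sampling
#'   metadata.
#' @export
pool_voxel_vectors <- function(studies, maps, cap_per_patient = 2000, seed = 1L) {
  stopifnot(length(studies) == length(maps), length(studies) >= 1)
  rows <- list(); pid <- list(); vix <- list()
  for (i in seq_along(studies)) {
    m <- maps[[i]]
    vox <- which(m$valid_mask != 0)
    if (length(vox) == 0) next
    take <- with_seed(derive_seed(seed, paste0("pool", i)), {
      if (length(vox) > cap_per_patient) sort(sample(vox, cap_per_patient)) else vox
    })
    rows[[length(rows) + 1]] <- cbind(
      wash_in = m$wash_in[take],
      wash_out = m$wash_out[take],
      wash_out_ratio = m$wash_out_ratio[take]
    )
    pid[[length(pid) + 1]] <- rep(studies[[i]]$patient_id, length(take))
    vix[[length(vix) + 1]] <- take
  }
  if (length(rows) == 0) stop("no study has valid perfusion voxels")
  structure(list(
    vectors = do.call(rbind, rows),
    patient_id = unlist(pid), voxel_index = unlist(vix),
    cap_per_patient = cap_per_patient, seed = seed
  ), class = "voxel_vector_set")
}

#' Mean silhouette coefficient of a labeled point set
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to the points of another
#' cluster; the silhouette is `(b - a) / max(a, b)` (Euclidean metric),
#' averaged over all points. Singleton clusters contribute 0, as usual.
#'
#' @param vectors n x p numeric matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_score <- function(vectors, labels) {
  vectors <- as.matrix(vectors)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette is undefined for a single cluster")
  n <- nrow(vectors)
  # mean distance from every point to every cluster, O(n^2) time but
  # computed blockwise without materializing a full dist object per pair
  counts <- tabulate(labels, k)
  s <- numeric(n)
  # cross-distance sums point -> cluster; coordinate-difference form keeps
  # full double precision (agrees with stats::dist to machine accuracy)
  dsum <- matrix(0, n, k)
  step <- 2048L
  for (start in seq(1L, n, by = step)) {
    idx <- start:min(start + step - 1L, n)
    d2 <- matrix(0, length(idx), n)
    for (c_ in seq_len(ncol(vectors))) {
      d2 <- d2 + outer(vectors[idx, c_], vectors[, c_], `-`)^2
    }
    dd <- sqrt(d2)
    for (g in seq_len(k)) {
      dsum[idx, g] <- rowSums(dd[, labels == g, drop = FALSE])
    }
  }
  for (i in seq_len(n)) {
    g <- labels[i]
    if (counts[g] == 1) { s[i] <- 0; next }
    a <- dsum[i, g] / (counts[g] - 1)
    b <- min(dsum[i, -g] / counts[-g])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Davies-Bouldin index of a labeled point set
#'
#' Mean over clusters of the worst-case ratio `(s_i + s_j) / d_ij`, where
#' `s_i` is the mean distance of cluster members to their centroid and
#' `d_ij` the distance between centroids. Lower is better. Coincident
#' centroids make the index infinite; callers treat that k as disqualified.
#'
#' @param vectors n x p numeric matrix.
#' @param labels Integer cluster labels (>= 2 nonempty clusters).
#' @return Scalar >= 0 (possibly `Inf`).
#' @export
davies_bouldin_index <- function(vectors, labels) {
  vectors <- as.matrix(vectors)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("Davies-Bouldin index needs >= 2 clusters")
  cent <- matrix(0, k, ncol(vectors))
  sprd <- numeric(k)
  for (g in seq_len(k)) {
    m <- vectors[labels == g, , drop = FALSE]
    cent[g, ] <- colMeans(m)
    sprd[g] <- mean(sqrt(rowSums((m - matrix(cent[g, ], nrow(m), ncol(m), byrow = TRUE))^2)))
  }
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratio <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      ratio <- max(ratio, if (dij > 0) (sprd[i] + sprd[j]) / dij else Inf)
    }
    r[i] <- ratio
  }
  mean(r)
}

#' Fit the population habitat model
#'
#' Standardizes the pooled vectors per dimension, runs k-means
#' (`nstart = 10`) for every k in `k_min..k_max`, scores each solution with
#' the silhouette coefficient (on a capped subsample when n is large, for
#' tractability) and the Davies-Bouldin index, and keeps the k with the
#' highest silhouette. If the DB-minimizing k differs, a divergence warning
#' is raised and silhouette wins. Cluster labels are canonicalized by
#' ascending centroid wash-in (ties: ascending wash-out).
#'
#' @param vector_set A [pool_voxel_vectors()] result.
#' @param k_min,k_max Cluster-count range (defaults 2 and 10).
#' @param seed RNG seed for k-means initialization and metric subsampling.
#' @param metric_cap Max points used for the silhouette computation
#'   (default 5000).
#' @return A `habitat_model`: `k`, `centroids` (canonical order, original
#'   perfusion units), `centroids_std`, `scaler`, `selection_table`,
#'   `fit_seed`.
#' @export
fit_habitat_model <- function(vector_set, k_min = 2, k_max = 10, seed = 1L,
                              metric_cap = 5000) {
  x <- vector_set$vectors
  n <- nrow(x)
  if (n < k_max) stop("need at least k_max pooled vectors")
  mu <- colMeans(x)
  sdv <- apply(x, 2, pop_sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  sub <- with_seed(derive_seed(seed, "metric"), {
    if (n > metric_cap) sort(sample.int(n, metric_cap)) else seq_len(n)
  })
  ks <- k_min:k_max
  tab <- data.frame(k = ks, inertia = NA_real_, silhouette = NA_real_,
                    davies_bouldin = NA_real_, disqualified = FALSE)
  fits <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    fit <- tryCatch(
      with_seed(derive_seed(seed, paste0("kmeans", k)), {
        withCallingHandlers(
          kmeans(xs, centers = k, nstart = 10, iter.max = 100),
          warning = function(w) {
            # the Quick-TRANSfer note on very large voxel pools is benign:
            # the Hartigan-Wong refinement stage hit its step cap after
            # convergence of the main loop
            if (grepl("Quick-TRANSfer", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
      }),
      error = function(e) NULL)  # e.g. fewer distinct points than centers
    fits[[j]] <- fit
    if (is.null(fit)) {
      tab$disqualified[j] <- TRUE
      next
    }
    tab$inertia[j] <- fit$tot.withinss
    if (length(unique(fit$cluster)) < k) {
      tab$disqualified[j] <- TRUE
      next
    }
    tab$silhouette[j] <- silhouette_score(xs[sub, , drop = FALSE], fit$cluster[sub])
    db <- davies_bouldin_index(xs, fit$cluster)
    tab$davies_bouldin[j] <- db
    if (!is.finite(db)) tab$disqualified[j] <- TRUE
  }
  ok <- !tab$disqualified & is.finite(tab$silhouette)
  if (!any(ok)) stop("every candidate k was disqualified")
  best <- which(ok)[which.max(tab$silhouette[ok])]
  db_ok <- ok & is.finite(tab$davies_bouldin)
  best_db <- which(db_ok)[which.min(tab$davies_bouldin[db_ok])]
  if (length(best_db) == 1 && best_db != best) {
    warning(sprintf(
      "silhouette (k = %d) and Davies-Bouldin (k = %d) disagree; using silhouette",
      tab$k[best], tab$k[best_db]))
  }
  fit <- fits[[best]]
  k <- tab$k[best]
  cent_std <- fit$centers
  cent_raw <- sweep(sweep(cent_std, 2, sdv, "*"), 2, mu, "+")
  ord <- order(cent_raw[, "wash_in"], cent_raw[, "wash_out"])
  structure(list(
    k = k,
    centroids = cent_raw[ord, , drop = FALSE],
    centroids_std = cent_std[ord, , drop = FALSE],
    label_order = ord,
    scaler = list(mean = mu, sd = sdv),
    selection_table = tab,
    fit_seed = seed
  ), class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("<habitat_model> k =", x$k, "\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Assign habitat labels to one study's tumor voxels
#'
#' Each valid voxel goes to the nearest model centroid in the standardized
#' perfusion space. Voxels with an undefined wash-out ratio (plateau) are
#' assigned using the wash-in / wash-out dimensions only, against the
#' centroid projections onto those dimensions, so every tumor voxel with
#' finite WI and WO receives a label.
#'
#' @param study A `dce_study`.
#' @param maps Its `perfusion_maps`.
#' @param model A fitted `habitat_model`.
#' @return A `habitat_mask`: `labels` (3-D integer array, 0 outside tumor)
#'   and `counts` (per-label voxel counts, length `model$k`).
#' @export
assign_habitats <- function(study, maps, model) {
  if (!inherits(model, "habitat_model")) stop("model must be a fitted habitat_model")
  d <- dim(study$tumor_mask)
  vox <- which(study$tumor_mask != 0)
  valid <- maps$valid_mask[vox] != 0
  if (!any(valid)) stop("study has no valid perfusion voxels")
  mu <- model$scaler$mean; sdv <- model$scaler$sd
  labels <- array(0L, d)
  assign_block <- function(idx, dims) {
    v <- cbind(maps$wash_in[idx], maps$wash_out[idx], maps$wash_out_ratio[idx])
    v <- v[, dims, drop = FALSE]
    vs <- sweep(sweep(v, 2, mu[dims]), 2, sdv[dims], "/")
    cen <- model$centroids_std[, dims, drop = FALSE]
    d2 <- outer(rowSums(vs^2), rowSums(cen^2), `+`) - 2 * tcrossprod(vs, cen)
    max.col(-d2, ties.method = "first")
  }
  iv <- vox[valid]
  labels[iv] <- assign_block(iv, 1:3)
  inv <- vox[!valid]
  if (length(inv) > 0) {
    fin <- is.finite(maps$wash_in[inv]) & is.finite(maps$wash_out[inv])
    if (any(fin)) labels[inv[fin]] <- assign_block(inv[fin], 1:2)
    if (any(!fin)) {
      # no usable perfusion information at all: nearest labeled neighbor
      lab_idx <- which(labels != 0)
      ci <- arrayInd(inv[!fin], d); cl <- arrayInd(lab_idx, d)
      for (i in seq_len(nrow(ci))) {
        dd <- rowSums((cl - matrix(ci[i, ], nrow(cl), 3, byrow = TRUE))^2)
        labels[inv[!fin][i]] <- labels[lab_idx[which.min(dd)]]
      }
    }
  }
  structure(list(
    labels = labels,
    counts = tabulate(labels[vox], nbins = model$k)
  ), class = "habitat_mask")
}
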