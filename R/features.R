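# Per-habitat radiomics feature extraction, missing-habitat imputation, and
# training-statistics z-scoring.
#
# Feature names follow the <filter>_<class>_<descriptor> grammar, e.g.
# "wavelet_HLL_firstorder_Skewness" or "log_sigma_2_0_mm_3D_glrlm_ShortRunEmphasis";
# build_feature_matrix() appends "_Habitat<i>".

#' Radiomics extraction configuration
#'
#' @param bin_width Fixed grey-level bin width used by the texture and
#'   histogram features. The default (25) assumes intensities scaled by
#'   `intensity_scale` after z-normalization.
#' @param intensity_scale Multiplier applied to the (z-normalized) image
#'   before extraction, so a unit-sd image spans a usable grey-level range.
#' @param log_sigmas Laplacian-of-Gaussian scales, mm.
#' @param wavelet Include the eight coiflet-1 sub-band images?
#' @param min_voxels Regions below this voxel count are treated as missing.
#' @return A `radiomics_config` list.
#' @export
radiomics_config <- function(bin_width = 25, intensity_scale = 100,
                             log_sigmas = c(2, 3, 4, 5), wavelet = TRUE,
                             min_voxels = 8) {
  stopifnot(bin_width > 0, min_voxels >= 1)
  structure(list(bin_width = bin_width, intensity_scale = intensity_scale,
                 log_sigmas = log_sigmas, wavelet = wavelet,
                 min_voxels = as.integer(min_voxels)),
            class = "radiomics_config")
}

firstorder_features <- function(v, bin_width, voxel_volume) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  g <- floor((v - min(v)) / bin_width) + 1
  p <- tabulate(g, max(g)) / n
  p <- p[p > 0]
  q <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  core <- v[v >= q[1] & v <= q[4]]
  c(
    Energy = sum(v^2),
    TotalEnergy = sum(v^2) * voxel_volume,
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(v),
    Mean = m,
    Median = median(v),
    InterquartileRange = q[3] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# Exposed-face surface area with the 2/3 Crofton-type correction
# (asymptotically unbiased for smooth convex digitized bodies).
mask_surface_area <- function(mask, spacing) {
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  m <- array(as.numeric(mask != 0), d)
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- sgn
      s <- shift_arr(m, off)
      s[is.na(s)] <- 0
      area <- area + face[ax] * sum(m == 1 & s == 0)
    }
  }
  area * 2 / 3
}

shape_features <- function(region_mask, spacing) {
  d <- dim(region_mask)
  vox <- which(region_mask != 0)
  n <- length(vox)
  vv <- prod(spacing)
  vol <- n * vv
  sa <- mask_surface_area(region_mask, spacing)
  coords <- sweep(arrayInd(vox, d), 2, spacing, "*")
  cv <- stats::cov(coords) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  # boundary voxels only, for the max diameter
  m <- array(as.numeric(region_mask != 0), d)
  nb <- array(0, d)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[ax] <- sgn
    s <- shift_arr(m, off); s[is.na(s)] <- 0
    nb <- nb + s
  }
  bvox <- which(m == 1 & nb < 6)
  bc <- sweep(arrayInd(bvox, d), 2, spacing, "*")
  maxd <- if (nrow(bc) > 1) {
    sq <- rowSums(bc^2)
    sqrt(max(outer(sq, sq, `+`) - 2 * tcrossprod(bc)))
  } else 0
  c(
    VoxelVolume = vol,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol,
    Sphericity = (pi^(1 / 3) * (6 * vol)^(2 / 3)) / sa,
    Maximum3DDiameter = maxd,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

# All filtered derivatives of an image, named by the pyradiomics-style
# filter prefix. Computed once per patient and shared across habitats.
filter_bank <- function(image, spacing, config) {
  bank <- list(original = image)
  for (s in config$log_sigmas) {
    nm <- sprintf("log_sigma_%s_mm_3D", gsub("\\.", "_", sprintf("%.1f", s)))
    bank[[nm]] <- log_filter3d(image, s, spacing)
  }
  if (isTRUE(config$wavelet)) {
    wb <- wavelet_decompose3d(image)
    for (b in names(wb)) bank[[paste0("wavelet_", b)]] <- wb[[b]]
  }
  bank
}

# Named feature vector for one region on one (possibly filtered) image.
region_image_features <- function(img, region_idx, bin_width, voxel_volume) {
  v <- img[region_idx]
  fo <- firstorder_features(v, bin_width, voxel_volume)
  qz <- quantize_region(img, region_idx, bin_width)
  n <- length(region_idx)
  glcm <- glcm_features(glcm_matrix(qz$q, qz$ng))
  glrlm <- glrlm_features(glrlm_matrix(qz$q, qz$ng), n)
  glszm <- glszm_features(glszm_matrix(qz$q, qz$ng), n)
  gldm <- gldm_features(gldm_matrix(qz$q, qz$ng), n)
  ngtdm <- ngtdm_features(qz$q, qz$ng)
  c(setNames(fo, paste0("firstorder_", names(fo))),
    setNames(glcm, paste0("glcm_", names(glcm))),
    setNames(glrlm, paste0("glrlm_", names(glrlm))),
    setNames(glszm, paste0("glszm_", names(glszm))),
    setNames(gldm, paste0("gldm_", names(gldm))),
    setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
}

#' Extract radiomics features from one region
#'
#' Computes shape features from the region mask plus first-order and
#' grey-level texture families (GLCM, GLRLM, GLSZM, GLDM, NGTDM) on the
#' original image and on each filtered derivative (Laplacian-of-Gaussian
#' scales and coiflet-1 wavelet sub-bands).
#'
#' @param image 3-D array; expected to be the z-normalized early-phase image
#'   (see [normalize_intensity()]) scaled by `config$intensity_scale`
#'   upstream, or any image if called directly.
#' @param region_mask 3-D 0/1 array (the habitat).
#' @param spacing Voxel spacing (mm).
#' @param config A [radiomics_config()].
#' @param bank Optional precomputed [filter bank][radiomics_config()] for
#'   the full image, to avoid recomputation across habitats.
#' @return Named numeric vector, or `NULL` if the region has fewer than
#'   `config$min_voxels` voxels (treated as a missing habitat).
#' @export
extract_region_features <- function(image, region_mask, spacing,
                                    config = radiomics_config(),
                                    bank = NULL) {
  if (!all(dim(image) == dim(region_mask))) stop("image/mask shape mismatch")
  region_idx <- which(region_mask != 0)
  if (length(region_idx) == 0) stop("region mask is empty")
  if (length(region_idx) < config$min_voxels) return(NULL)
  if (is.null(bank)) bank <- filter_bank(image, spacing, config)
  vv <- prod(spacing)
  sh <- shape_features(region_mask, spacing)
  out <- setNames(sh, paste0("original_shape_", names(sh)))
  # crop to the region bounding box: texture neighborhoods never cross the
  # region boundary, so this is exact and much faster
  ci <- arrayInd(region_idx, dim(region_mask))
  rng <- lapply(1:3, function(ax) min(ci[, ax]):max(ci[, ax]))
  sub_mask <- region_mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub_idx <- which(sub_mask != 0)
  for (fname in names(bank)) {
    sub_img <- bank[[fname]][rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    fv <- region_image_features(sub_img, sub_idx, config$bin_width, vv)
    out <- c(out, setNames(fv, paste0(fname, "_", names(fv))))
  }
  out
}

#' Build the patients-by-features matrix over habitat subregions
#'
#' For each patient, features are extracted once per habitat from the
#' z-normalized early-phase image (times `config$intensity_scale`); habitats
#' absent (or below the minimum size) in a patient produce `NA` for that
#' habitat's full column block. Column names carry the habitat suffix
#' (`..._Habitat<i>`).
#'
#' @param studies List of `dce_study`.
#' @param habitat_masks List of `habitat_mask` aligned with `studies`.
#' @param model The shared `habitat_model` (fixes k).
#' @param config A [radiomics_config()].
#' @return A numeric matrix (rows = patients) of class `feature_matrix`
#'   with attributes `her2` (labels), `k`, `per_region_count`, `config`.
#' @export
build_feature_matrix <- function(studies, habitat_masks, model,
                                 config = radiomics_config()) {
  stopifnot(length(studies) == length(habitat_masks))
  k <- model$k
  rows <- vector("list", length(studies))
  template <- NULL
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    hm <- habitat_masks[[i]]
    if (max(hm$labels) > k) stop("habitat mask labels exceed model k")
    img <- normalize_intensity(s$phase_early, s$tumor_mask) * config$intensity_scale
    bank <- filter_bank(img, s$spacing, config)
    per_hab <- vector("list", k)
    for (h in seq_len(k)) {
      rm <- array(0L, dim(hm$labels)); rm[hm$labels == h] <- 1L
      if (sum(rm) < config$min_voxels) { per_hab[[h]] <- NULL; next }
      per_hab[[h]] <- extract_region_features(img, rm, s$spacing, config, bank)
    }
    filled <- which(!vapply(per_hab, is.null, logical(1)))
    if (length(filled) == 0) stop("patient ", s$patient_id, " has no usable habitat")
    if (is.null(template)) template <- names(per_hab[[filled[1]]])
    row <- rep(NA_real_, length(template) * k)
    names(row) <- as.vector(vapply(seq_len(k), function(h)
      paste0(template, "_Habitat", h), character(length(template))))
    for (h in filled) {
      row[paste0(template, "_Habitat", h)] <- per_hab[[h]][template]
    }
    rows[[i]] <- row
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(studies, `[[`, character(1), "patient_id")
  structure(mat,
            her2 = vapply(studies, `[[`, character(1), "her2"),
            k = k, per_region_count = length(template),
            config = config, class = c("feature_matrix", "matrix", "array"))
}

#' Expected feature-matrix column count
#'
#' The column total is always `k` habitats times the per-region feature
#' count (each habitat contributes one full block).
#'
#' @param k Habitat count.
#' @param per_region_count Features extracted per region.
#' @return Integer column total.
#' @export
expected_feature_columns <- function(k, per_region_count) {
  as.integer(k) * as.integer(per_region_count)
}

#' Parse a feature name into its components
#'
#' @param names Character vector of `<filter>_<class>_<descriptor>_Habitat<i>`
#'   names.
#' @return Data frame with `filter`, `class`, `descriptor`, `habitat`.
#' @export
parse_feature_name <- function(names) {
  hab <- as.integer(sub(".*_Habitat(\\d+)$", "\\1", names))
  rest <- sub("_Habitat\\d+$", "", names)
  classes <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
  cls <- rep(NA_character_, length(rest))
  filt <- desc <- rep(NA_character_, length(rest))
  for (cl in classes) {
    hit <- grepl(paste0("_", cl, "_"), rest) & is.na(cls)
    cls[hit] <- cl
    filt[hit] <- sub(paste0("_", cl, "_.*$"), "", rest[hit])
    desc[hit] <- sub(paste0("^.*_", cl, "_"), "", rest[hit])
  }
  if (anyNA(cls)) stop("unparseable feature name(s): ",
                       paste(head(names[is.na(cls)]), collapse = ", "))
  data.frame(filter = filt, class = cls, descriptor = desc, habitat = hab,
             stringsAsFactors = FALSE)
}

#' KNN imputation of missing habitat features
#'
#' Missing entries are replaced by the unweighted mean of the
#' `n_neighbors` nearest *training* rows (Euclidean distance over the
#' columns observed in both rows, standardized by training statistics).
#' Training rows form the neighbor pool for every row, so test rows never
#' borrow from each other.
#'
#' @param matrix A `feature_matrix` (or plain matrix) with `NA` markers.
#' @param train_rows Integer or logical index of training rows.
#' @param n_neighbors Neighbor count (default 5).
#' @return Matrix of the same shape with `NA`s filled.
#' @export
impute_missing <- function(matrix, train_rows = seq_len(nrow(matrix)),
                           n_neighbors = 5) {
  m <- unclass(matrix)
  tr <- m[train_rows, , drop = FALSE]
  miss_col <- colSums(!is.na(tr)) == 0
  if (any(miss_col)) {
    stop("column(s) missing in all training rows: ",
         paste(head(colnames(m)[miss_col], 3), collapse = ", "))
  }
  if (!anyNA(m)) return(matrix)
  mu <- colMeans(tr, na.rm = TRUE)
  sdv <- apply(tr, 2, function(x) pop_sd(x[!is.na(x)]))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  std <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  tr_s <- std(tr)
  m_s <- std(m)
  out <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    obs <- !is.na(m_s[i, ])
    d2 <- vapply(seq_len(nrow(tr_s)), function(j) {
      both <- obs & !is.na(tr_s[j, ])
      if (!any(both)) return(Inf)
      mean((m_s[i, both] - tr_s[j, both])^2)
    }, numeric(1))
    # exclude self when the row is itself a training row
    self <- which(rownames(tr) == rownames(m)[i])
    if (length(self) > 0 && !is.null(rownames(m))) d2[self] <- Inf
    nn <- order(d2)[seq_len(min(n_neighbors, sum(is.finite(d2))))]
    for (jcol in which(is.na(m[i, ]))) {
      vals <- tr[nn, jcol]
      vals <- vals[!is.na(vals)]
      out[i, jcol] <- if (length(vals) > 0) mean(vals) else mu[jcol]
    }
  }
  attributes(out) <- attributes(matrix)
  out
}

#' Training-cohort feature standardization statistics
#'
#' @param matrix Feature matrix (post-imputation).
#' @param train_rows Training-row index.
#' @return A `train_stats` list: per-column `mean` and population `sd`.
#' @export
compute_train_stats <- function(matrix, train_rows = seq_len(nrow(matrix))) {
  tr <- unclass(matrix)[train_rows, , drop = FALSE]
  structure(list(
    mean = colMeans(tr),
    sd = apply(tr, 2, pop_sd),
    n_train = nrow(tr)
  ), class = "train_stats")
}

#' Z-score features against training statistics
#'
#' `(x - mean) / sd` per column using *training* mean/sd only; zero-sd
#' columns map to 0 and are flagged in attribute `degenerate`.
#'
#' @param matrix Feature matrix.
#' @param train_stats A [compute_train_stats()] result.
#' @return Transformed matrix (same shape) with attribute `degenerate`.
#' @export
zscore_transform <- function(matrix, train_stats) {
  m <- unclass(matrix)
  if (!identical(colnames(m), names(train_stats$mean)) &&
      !(is.null(colnames(m)) && length(train_stats$mean) == ncol(m))) {
    if (ncol(m) != length(train_stats$mean)) stop("stats/columns mismatch")
  }
  sdv <- train_stats$sd
  degen <- !is.finite(sdv) | sdv == 0
  sdv[degen] <- 1
  out <- sweep(sweep(m, 2, train_stats$mean), 2, sdv, "/")
  out[, degen] <- 0
  attr(out, "her2") <- attr(matrix, "her2")
  attr(out, "degenerate") <- colnames(m)[degen]
  out
}
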