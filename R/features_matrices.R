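# Grey-level texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM) computed on
# a quantized region image, with all 26-connected 3-D directions merged into
# a single matrix per family.

# Shift a 3-D array by an integer offset; positions whose source falls
# outside the array become NA. out[i] = q[i + off].
shift_arr <- function(q, off) {
  d <- dim(q)
  out <- array(NA_real_, d)
  xs <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  ys <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  zs <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
  if (length(xs) < 1 || length(ys) < 1 || length(zs) < 1) return(out)
  out[xs, ys, zs] <- q[xs + off[1], ys + off[2], zs + off[3]]
  out
}

# The 13 unique (half-space) 26-connectivity direction offsets.
offsets13 <- function() {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      offs[[length(offs) + 1]] <- v
    }
  }
  offs
}

# Quantize in-region intensities with a fixed bin width anchored at the
# region minimum; returns the quantized array (NA outside region) and Ng.
quantize_region <- function(image, region_idx, bin_width) {
  v <- image[region_idx]
  g <- floor((v - min(v)) / bin_width) + 1
  q <- array(NA_real_, dim(image))
  q[region_idx] <- g
  list(q = q, ng = max(g))
}

glcm_matrix <- function(q, ng) {
  P <- matrix(0, ng, ng)
  for (off in offsets13()) {
    s <- shift_arr(q, off)
    ok <- !is.na(q) & !is.na(s)
    if (!any(ok)) next
    idx <- (q[ok] - 1) * ng + s[ok]
    cnt <- tabulate(idx, ng * ng)
    m <- matrix(cnt, ng, ng, byrow = TRUE)
    P <- P + m + t(m)  # symmetric: both scan directions
  }
  P
}

glcm_features <- function(P) {
  out <- setNames(rep(0, 18), c(
    "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
    "DifferenceVariance", "Id", "Idm", "InverseVariance", "JointEnergy",
    "JointEntropy", "MaximumProbability", "SumAverage", "SumEntropy",
    "SumSquares"))
  tot <- sum(P)
  if (tot == 0) { out["Correlation"] <- 1; return(out) }
  p <- P / tot
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  dif <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(p[dif == k]), numeric(1))
  sm <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(p[sm == k]), numeric(1))
  nz <- p > 0
  out["Autocorrelation"] <- sum(i * j * p)
  out["ClusterTendency"] <- sum((i + j - 2 * mu)^2 * p)
  out["ClusterShade"] <- sum((i + j - 2 * mu)^3 * p)
  out["ClusterProminence"] <- sum((i + j - 2 * mu)^4 * p)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlation"] <- if (sig2 > 0) (out["Autocorrelation"] - mu^2) / sig2 else 1
  da <- sum((0:(ng - 1)) * pd)
  out["DifferenceAverage"] <- da
  out["DifferenceVariance"] <- sum(((0:(ng - 1)) - da)^2 * pd)
  out["DifferenceEntropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  out["Id"] <- sum(p / (1 + dif))
  out["Idm"] <- sum(p / (1 + dif^2))
  offdiag <- dif > 0
  out["InverseVariance"] <- sum(p[offdiag] / dif[offdiag]^2)
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- -sum(p[nz] * log2(p[nz]))
  out["MaximumProbability"] <- max(p)
  out["SumAverage"] <- sum((2:(2 * ng)) * ps)
  out["SumEntropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  out["SumSquares"] <- sig2
  out
}

# Run-length matrix, all 13 directions merged. Runs are found by ordering
# region voxels along each direction's lines and breaking on value change or
# positional gaps.
glrlm_matrix <- function(q, ng) {
  d <- dim(q)
  vox <- which(!is.na(q))
  coords <- arrayInd(vox, d)
  vals <- q[vox]
  maxlen <- max(d)
  P <- matrix(0, ng, maxlen)
  for (off in offsets13()) {
    t_pos <- as.vector(coords %*% off)
    line_key <- coords - outer(t_pos, off)
    o <- order(line_key[, 1], line_key[, 2], line_key[, 3], t_pos)
    lk <- line_key[o, , drop = FALSE]
    tp <- t_pos[o]
    vv <- vals[o]
    n <- length(vv)
    new_run <- c(TRUE,
      lk[-1, 1] != lk[-n, 1] | lk[-1, 2] != lk[-n, 2] | lk[-1, 3] != lk[-n, 3] |
      tp[-1] != tp[-n] + 1 | vv[-1] != vv[-n])
    run_id <- cumsum(new_run)
    lens <- tabulate(run_id)
    g <- vv[new_run]
    for (u in seq_along(lens)) P[g[u], lens[u]] <- P[g[u], lens[u]] + 1
  }
  P[, seq_len(max(1, max(which(colSums(P) > 0)))), drop = FALSE]
}

# Shared features for matrices indexed by (grey level, size-like quantity).
gl_size_features <- function(P, n_voxels, n_norm, prefix_small, prefix_large,
                             size_name, extra_names) {
  tot <- sum(P)
  ng <- nrow(P); ns <- ncol(P)
  g <- seq_len(ng); s <- seq_len(ns)
  p <- P / tot
  pg <- rowSums(p); ps <- colSums(p)
  Sg <- rowSums(P); Ss <- colSums(P)
  inv_s2 <- matrix(1 / s^2, ng, ns, byrow = TRUE)
  s2 <- matrix(s^2, ng, ns, byrow = TRUE)
  inv_g2 <- matrix(1 / g^2, ng, ns)
  g2 <- matrix(g^2, ng, ns)
  mug <- sum(g * pg); mus <- sum(s * ps)
  nzp <- p > 0
  out <- c(
    sum(p * inv_s2),                    # small emphasis
    sum(p * s2),                        # large emphasis
    sum(Sg^2) / tot,                    # GrayLevelNonUniformity
    sum(Sg^2) / tot^2,                  # ...Normalized
    sum(Ss^2) / tot,                    # size non-uniformity
    sum(Ss^2) / tot^2,                  # ...Normalized
    tot / n_norm,                       # percentage
    sum((matrix(g, ng, ns) - mug)^2 * p),   # GrayLevelVariance
    sum((matrix(s, ng, ns, byrow = TRUE) - mus)^2 * p), # size variance
    -sum(p[nzp] * log2(p[nzp])),        # entropy
    sum(p * inv_g2),                    # LowGrayLevelEmphasis
    sum(p * g2),                        # HighGrayLevelEmphasis
    sum(p * inv_g2 * inv_s2),
    sum(p * g2 * inv_s2),
    sum(p * inv_g2 * s2),
    sum(p * g2 * s2)
  )
  names(out) <- extra_names
  out
}

glrlm_features <- function(P, n_voxels) {
  gl_size_features(P, n_voxels, n_norm = n_voxels * 13,
    extra_names = c("ShortRunEmphasis", "LongRunEmphasis",
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
      "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

# Size-zone matrix: zones are 26-connected components of constant grey level.
glszm_matrix <- function(q, ng) {
  d <- dim(q)
  vox <- which(!is.na(q))
  vmap <- integer(prod(d)); vmap[vox] <- seq_along(vox)
  edges <- list()
  for (off in offsets13()) {
    s <- shift_arr(q, off)
    ok <- which(!is.na(q) & !is.na(s) & q == s)
    if (length(ok) == 0) next
    # linear index of the shifted source voxel (in bounds because s is non-NA)
    tgt <- ok + off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
    edges[[length(edges) + 1]] <- cbind(vmap[ok], vmap[tgt])
  }
  if (length(edges) > 0) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
    comp <- igraph::components(g)
    zone_of <- comp$membership
  } else {
    zone_of <- seq_along(vox)
  }
  sizes <- tabulate(zone_of)
  # grey level of each zone = value of any member voxel
  zg <- numeric(max(zone_of))
  zg[zone_of] <- q[vox]
  P <- matrix(0, ng, max(sizes))
  for (z in seq_along(sizes)) P[zg[z], sizes[z]] <- P[zg[z], sizes[z]] + 1
  P
}

glszm_features <- function(P, n_voxels) {
  gl_size_features(P, n_voxels, n_norm = n_voxels,
    extra_names = c("SmallAreaEmphasis", "LargeAreaEmphasis",
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
      "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

all_offsets26 <- function() {
  offs <- offsets13()
  c(offs, lapply(offs, function(o) -o))
}

# Dependence matrix: for each voxel, the number of 26-neighbors with the
# same quantized level (alpha = 0), plus the voxel itself.
gldm_matrix <- function(q, ng) {
  dep <- array(0L, dim(q))
  for (off in all_offsets26()) {
    s <- shift_arr(q, off)
    eq <- !is.na(q) & !is.na(s) & q == s
    dep <- dep + eq
  }
  vox <- which(!is.na(q))
  dmax <- max(dep[vox]) + 1L
  P <- matrix(0, ng, dmax)
  for (i in vox) P[q[i], dep[i] + 1L] <- P[q[i], dep[i] + 1L] + 1
  P
}

gldm_features <- function(P, n_voxels) {
  # the shared helper fills 16 generic slots; the dependence family keeps 14
  # (grey-level-NU-normalized and the percentage slot are not part of it)
  f <- gl_size_features(P, n_voxels, n_norm = n_voxels,
    extra_names = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", ".drop1",
      "DependenceNonUniformity", "DependenceNonUniformityNormalized",
      ".drop2", "GrayLevelVariance", "DependenceVariance",
      "DependenceEntropy", "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"))
  f[!startsWith(names(f), ".drop")]
}

ngtdm_features <- function(q, ng) {
  nbr_sum <- array(0, dim(q))
  nbr_cnt <- array(0L, dim(q))
  for (off in all_offsets26()) {
    s <- shift_arr(q, off)
    hit <- !is.na(s)
    nbr_sum[hit] <- nbr_sum[hit] + s[hit]
    nbr_cnt <- nbr_cnt + hit
  }
  vox <- which(!is.na(q) & nbr_cnt > 0)
  A <- nbr_sum[vox] / nbr_cnt[vox]
  g <- q[vox]
  N <- length(vox)
  n_g <- tabulate(g, ng)
  s_g <- vapply(seq_len(ng), function(l) sum(abs(l - A[g == l])), numeric(1))
  p_g <- n_g / N
  act <- which(p_g > 0)
  ngp <- length(act)
  out <- setNames(rep(0, 5), c("Coarseness", "Contrast", "Busyness",
                               "Complexity", "Strength"))
  denom <- sum(p_g * s_g)
  out["Coarseness"] <- if (denom > 0) 1 / denom else 1e6
  if (ngp > 1) {
    pij <- outer(p_g[act], p_g[act])
    dij2 <- outer(act, act, function(a, b) (a - b)^2)
    out["Contrast"] <- (sum(pij * dij2) / (ngp * (ngp - 1))) * (sum(s_g) / N)
    bd <- sum(abs(outer(act * p_g[act], act * p_g[act], `-`)))
    out["Busyness"] <- if (bd > 0) denom / bd else 0
    cplx <- 0
    for (ii in act) for (jj in act) {
      cplx <- cplx + abs(ii - jj) * (p_g[ii] * s_g[ii] + p_g[jj] * s_g[jj]) /
        (p_g[ii] + p_g[jj])
    }
    out["Complexity"] <- cplx / N
    num <- sum(outer(p_g[act], p_g[act], `+`) * dij2)
    out["Strength"] <- if (sum(s_g) > 0) num / sum(s_g) else 0
  }
  out
}
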