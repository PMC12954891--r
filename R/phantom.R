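# Synthetic DCE-MRI phantom cohorts with planted perfusion habitats.
#
# Each phantom patient carries three co-registered phase volumes
# (pre-contrast, early ~2 min, delayed ~6 min post-injection), a tumor mask,
# a planted habitat label volume, and a ternary HER2 label whose signal is
# encoded in the habitat composition and per-habitat noise texture.

#' Kinetic signature of one perfusion habitat
#'
#' The triplet of mean signal intensities (arbitrary units) of a habitat in
#' the pre-contrast, early and delayed DCE phases. All three must be strictly
#' positive; absolute scale is irrelevant downstream because the perfusion
#' parameters are ratios.
#'
#' @param s_pre,s_early,s_delayed Positive scalars (a.u.).
#' @return A `kinetic_signature` object.
#' @export
kinetic_signature <- function(s_pre, s_early, s_delayed) {
  v <- c(s_pre = s_pre, s_early = s_early, s_delayed = s_delayed)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("kinetic signature values must be strictly positive and finite")
  }
  structure(as.list(v), class = "kinetic_signature")
}

#' Canonical habitat kinetic signatures
#'
#' A library of distinct enhancement patterns: rapid wash-in with wash-out,
#' plateau, persistent (delayed) enhancement, slow weak enhancement, and very
#' rapid strong enhancement. The first `k` are used when planting `k` habitats.
#'
#' @param k Number of signatures (2..5).
#' @return List of [kinetic_signature()] objects.
#' @export
default_signatures <- function(k = 4) {
  lib <- list(
    kinetic_signature(100, 300, 220), # rapid wash-in, clear wash-out
    kinetic_signature(100, 220, 220), # moderate wash-in, plateau
    kinetic_signature(100, 160, 220), # persistent enhancement
    kinetic_signature(100, 130, 135), # slow, weak enhancement
    kinetic_signature(100, 400, 260)  # very rapid, strong enhancement
  )
  if (k < 1 || k > length(lib)) stop("k must be between 1 and ", length(lib))
  lib[seq_len(k)]
}

signature_matrix <- function(signatures) {
  m <- t(vapply(signatures, function(s) c(s$s_pre, s$s_early, s$s_delayed), numeric(3)))
  colnames(m) <- c("pre", "early", "delayed")
  m
}

#' Per-class habitat effects
#'
#' HER2 class signal is planted through (a) class-specific habitat mixing
#' proportions and (b) a class- and habitat-specific spatial correlation
#' length of the acquisition noise (texture scale, voxels). HER2-zero tumors
#' are dominated by early-enhancing habitats with fine texture; HER2-positive
#' tumors by late/slow habitats with coarse texture; HER2-low sits between
#' with a uniform mix.
#'
#' @param k Number of habitats.
#' @return Named list (`zero`, `low`, `positive`) of lists with elements
#'   `mixing` (k proportions summing to 1) and `texture_sigma` (k noise
#'   smoothing sds, voxels).
#' @export
default_class_effects <- function(k = 4) {
  dec <- (k:1)^1.5; inc <- (1:k)^1.5
  base <- seq(0.8, 1.2, length.out = k)
  list(
    zero     = list(mixing = dec / sum(dec), texture_sigma = 0.2 * base),
    low      = list(mixing = rep(1 / k, k),  texture_sigma = 0.6 * base),
    positive = list(mixing = inc / sum(inc), texture_sigma = 1.0 * base)
  )
}

#' Class effects with no class signal (null control)
#'
#' All three classes share the same mixing proportions and texture scale, so
#' habitat composition and texture carry no information about HER2 status.
#'
#' @param k Number of habitats.
#' @return Same structure as [default_class_effects()].
#' @export
null_class_effects <- function(k = 4) {
  e <- list(mixing = rep(1 / k, k), texture_sigma = rep(0.6, k))
  list(zero = e, low = e, positive = e)
}

#' Phantom cohort configuration
#'
#' @param n_patients Cohort size.
#' @param class_probs Length-3 probabilities for (zero, low, positive),
#'   summing to 1.
#' @param k_true Planted habitat count (>= 1).
#' @param signatures List of `k_true` [kinetic_signature()] objects.
#' @param class_effects Per-class mixing/texture, as [default_class_effects()].
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing Physical voxel spacing (mm).
#' @param radius_range Tumor semi-axis range (voxels).
#' @param background Background tissue baseline signal (a.u.).
#' @param stratified If `TRUE` (default) class counts are allocated
#'   proportionally (largest-remainder rounding) rather than sampled.
#' @param seed RNG seed for the whole cohort.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 90,
                           class_probs = c(1, 1, 1) / 3,
                           k_true = 4,
                           signatures = default_signatures(k_true),
                           class_effects = default_class_effects(k_true),
                           noise_sd = 5,
                           grid_shape = c(32L, 32L, 32L),
                           spacing = c(1, 1, 1),
                           radius_range = c(6, 10),
                           background = 20,
                           stratified = TRUE,
                           seed = 1L) {
  stopifnot(n_patients >= 1, length(class_probs) == 3, length(grid_shape) == 3)
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (k_true < 1) stop("k_true must be >= 1")
  if (length(signatures) != k_true) stop("need one signature per planted habitat")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (cl in her2_levels()) {
    eff <- class_effects[[cl]]
    if (is.null(eff)) stop("class_effects missing class ", cl)
    if (length(eff$mixing) != k_true || abs(sum(eff$mixing) - 1) > 1e-8) {
      stop("class_effects$", cl, "$mixing must have k_true entries summing to 1")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), class_probs = class_probs,
    k_true = as.integer(k_true), signatures = signatures,
    class_effects = class_effects, noise_sd = noise_sd,
    grid_shape = as.integer(grid_shape), spacing = spacing,
    radius_range = radius_range, background = background,
    stratified = isTRUE(stratified), seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Generate a connected, roughly ellipsoidal tumor mask
#'
#' Semi-axes are drawn from `radius_range`; the boundary is perturbed by a
#' smooth random field to avoid a perfectly analytic shape, and the largest
#' connected component is kept so the mask is guaranteed connected.
#'
#' @param grid_shape Integer length-3 grid.
#' @param radius_range Length-2 semi-axis range in voxels.
#' @param seed RNG seed.
#' @return 3-D 0/1 integer array.
#' @export
generate_tumor_mask <- function(grid_shape, radius_range = c(6, 10), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (2 * max(radius_range) + 2 > min(grid_shape)) {
    stop("configuration error: radius_range does not fit inside grid_shape")
  }
  with_seed(seed, {
    radii <- runif(3, radius_range[1], radius_range[2])
    ctr <- grid_shape / 2 + runif(3, -1, 1)
    ax <- lapply(1:3, function(i) seq_len(grid_shape[i]))
    # normalized ellipsoid distance field
    xs <- (ax[[1]] - ctr[1]) / radii[1]
    ys <- (ax[[2]] - ctr[2]) / radii[2]
    zs <- (ax[[3]] - ctr[3]) / radii[3]
    d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
    # smooth boundary perturbation (~10% of radius)
    pert <- gaussian_smooth3d(array(rnorm(prod(grid_shape)), grid_shape), 2.5)
    pert <- pert / max(pop_sd(as.vector(pert)), 1e-12)
    mask <- (sqrt(d2) <= 1 + 0.1 * pert) * 1L
    mask <- largest_component(mask)
    if (sum(mask) < 200) stop("generated mask too small (< 200 voxels)")
    storage.mode(mask) <- "integer"
    mask
  })
}

# For linear indices `idx` (1-based) in a d[1]xd[2]xd[3] grid, return the
# valid 6-neighbors as a list of index vectors aligned with `idx`.
neighbors6 <- function(idx, d) {
  i0 <- idx - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  out <- vector("list", 6)
  out[[1]] <- ifelse(x > 0L, idx - 1L, NA_integer_)
  out[[2]] <- ifelse(x < d[1] - 1L, idx + 1L, NA_integer_)
  out[[3]] <- ifelse(y > 0L, idx - d[1], NA_integer_)
  out[[4]] <- ifelse(y < d[2] - 1L, idx + d[1], NA_integer_)
  out[[5]] <- ifelse(z > 0L, idx - d[1] * d[2], NA_integer_)
  out[[6]] <- ifelse(z < d[3] - 1L, idx + d[1] * d[2], NA_integer_)
  out
}

# Keep the largest 6-connected component of a binary array.
largest_component <- function(mask) {
  d <- dim(mask)
  idx <- which(mask != 0)
  if (length(idx) == 0) return(mask)
  nb <- neighbors6(idx, d)
  inmask <- logical(prod(d)); inmask[idx] <- TRUE
  edges <- NULL
  for (k in 1:6) {
    ok <- !is.na(nb[[k]]) & inmask[pmax(nb[[k]], 1L)]
    ok[is.na(ok)] <- FALSE
    if (any(ok)) edges <- rbind(edges, cbind(idx[ok], nb[[k]][ok]))
  }
  vmap <- integer(prod(d)); vmap[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(cbind(vmap[edges[, 1]], vmap[edges[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- array(0L, d); out[keep] <- 1L
  out
}

#' Plant spatially coherent habitat labels inside a tumor mask
#'
#' Competitive region growing from `k_true` mutually distant seed voxels:
#' at each step the habitat with the largest deficit relative to its target
#' mixing proportion claims one voxel from its growth frontier, so realized
#' proportions track `mixing_props` closely while labels stay contiguous.
#'
#' @param mask 3-D 0/1 array.
#' @param k_true Number of habitats.
#' @param mixing_props Length-`k_true` proportions summing to 1.
#' @param seed RNG seed.
#' @return 3-D integer array: 0 outside the tumor, 1..k inside.
#' @export
plant_habitats <- function(mask, k_true, mixing_props, seed = 1L) {
  d <- dim(mask)
  vox <- which(mask != 0)
  n <- length(vox)
  if (length(mixing_props) != k_true || abs(sum(mixing_props) - 1) > 1e-8) {
    stop("mixing_props must have k_true entries summing to 1")
  }
  if (k_true > n) stop("k_true exceeds tumor voxel count")
  labels <- integer(prod(d))
  if (k_true == 1) {
    labels[vox] <- 1L
    return(array(labels, d))
  }
  with_seed(seed, {
    # farthest-point seed selection among tumor voxels
    coords <- arrayInd(vox, d)
    first <- sample.int(n, 1)
    seeds <- first
    dmin <- rowSums((coords - matrix(coords[first, ], n, 3, byrow = TRUE))^2)
    while (length(seeds) < k_true) {
      nxt <- which.max(dmin)
      seeds <- c(seeds, nxt)
      dd <- rowSums((coords - matrix(coords[nxt, ], n, 3, byrow = TRUE))^2)
      dmin <- pmin(dmin, dd)
    }
    counts <- integer(k_true)
    frontier <- vector("list", k_true)
    for (h in seq_len(k_true)) {
      labels[vox[seeds[h]]] <- h
      counts[h] <- 1L
      frontier[[h]] <- vox[seeds[h]]
    }
    inmask <- logical(prod(d)); inmask[vox] <- TRUE
    n_assigned <- k_true
    total <- n
    while (n_assigned < total) {
      deficit <- mixing_props - counts / total
      ord <- order(deficit, decreasing = TRUE)
      grew <- FALSE
      for (h in ord) {
        # pop frontier entries until an unlabeled neighbor is found
        while (length(frontier[[h]]) > 0) {
          pick <- sample.int(length(frontier[[h]]), 1)
          v <- frontier[[h]][pick]
          nb <- unlist(neighbors6(v, d))
          nb <- nb[!is.na(nb)]
          nb <- nb[inmask[nb] & labels[nb] == 0L]
          if (length(nb) == 0) {
            frontier[[h]] <- frontier[[h]][-pick]
            next
          }
          w <- nb[sample.int(length(nb), 1)]
          labels[w] <- h
          counts[h] <- counts[h] + 1L
          n_assigned <- n_assigned + 1L
          frontier[[h]] <- c(frontier[[h]], w)
          grew <- TRUE
          break
        }
        if (grew) break
      }
      if (!grew) {
        # isolated unlabeled pockets: attach to nearest seed label
        left <- vox[labels[vox] == 0L]
        lc <- arrayInd(left, d)
        sc <- coords[seeds, , drop = FALSE]
        for (i in seq_along(left)) {
          dd <- rowSums((sc - matrix(lc[i, ], k_true, 3, byrow = TRUE))^2)
          labels[left[i]] <- which.min(dd)
        }
        n_assigned <- total
      }
    }
  })
  array(labels, d)
}

#' Simulate the three DCE phase volumes from planted habitats
#'
#' Each tumor voxel takes its habitat's kinetic signature value plus additive
#' Gaussian noise; background voxels take a fixed low baseline plus noise.
#' When `texture_sigma` is supplied (one value per habitat), the in-habitat
#' noise is spatially smoothed white noise rescaled to sd `noise_sd`,
#' emulating class-dependent texture; with `texture_sigma = NULL` the noise
#' is i.i.d.
#'
#' @param mask 3-D 0/1 tumor mask.
#' @param habitat_truth 3-D integer labels (0 outside tumor).
#' @param signatures List of [kinetic_signature()], one per label.
#' @param noise_sd Additive noise sd (a.u.).
#' @param seed RNG seed.
#' @param texture_sigma Optional per-habitat smoothing sd (voxels).
#' @param background Background baseline signal (a.u.).
#' @return List with `phase_pre`, `phase_early`, `phase_delayed`.
#' @export
simulate_phases <- function(mask, habitat_truth, signatures, noise_sd = 5,
                            seed = 1L, texture_sigma = NULL, background = 20) {
  d <- dim(mask)
  labs <- sort(unique(habitat_truth[habitat_truth > 0]))
  if (length(labs) > 0 && max(labs) > length(signatures)) {
    stop("missing kinetic signature for habitat label ", max(labs))
  }
  sig <- signature_matrix(signatures)
  phases <- with_seed(seed, {
    out <- list()
    for (p in 1:3) {
      vol <- array(background, d)
      for (h in labs) vol[habitat_truth == h] <- sig[h, p]
      if (noise_sd > 0) {
        noise <- array(rnorm(prod(d), sd = noise_sd), d)
        if (!is.null(texture_sigma)) {
          for (h in labs) {
            s <- texture_sigma[h]
            if (s > 0) {
              sm <- gaussian_smooth3d(array(rnorm(prod(d)), d), s)
              k1 <- gauss_kernel(s)
              sm <- sm / sqrt(sum(k1^2))^3  # restore unit variance
              noise[habitat_truth == h] <- noise_sd * sm[habitat_truth == h]
            }
          }
        }
        vol <- vol + noise
      }
      out[[p]] <- vol
    }
    out
  })
  names(phases) <- c("phase_pre", "phase_early", "phase_delayed")
  phases
}

#' Generate a synthetic DCE cohort
#'
#' @param config A [phantom_config()].
#' @param out_dir Optional directory; when given, each study's phases, mask
#'   and truth labels are written as NIfTI together with a cohort manifest
#'   CSV and the configuration as YAML.
#' @param id_prefix Prefix for patient identifiers.
#' @return List of `dce_study` objects (see [phantom_config()] for fields).
#' @export
generate_cohort <- function(config, out_dir = NULL, id_prefix = "P") {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_patients
  lv <- her2_levels()
  labels <- with_seed(derive_seed(config$seed, "labels"), {
    if (config$stratified) {
      cnt <- floor(n * config$class_probs)
      rem <- n - sum(cnt)
      if (rem > 0) {
        frac <- n * config$class_probs - cnt
        cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
          cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
      }
      sample(rep(lv, times = cnt))
    } else {
      draw <- sample(lv, n, replace = TRUE, prob = config$class_probs)
      if (n >= 30 && length(unique(draw)) < 3) {
        # degenerate draw: fall back to stratified allocation
        cnt <- pmax(1, round(n * config$class_probs))
        cnt[1] <- n - sum(cnt[-1])
        draw <- sample(rep(lv, times = cnt))
      }
      draw
    }
  })
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("%s%03d", id_prefix, i)
    cls <- labels[i]
    eff <- config$class_effects[[cls]]
    mask <- generate_tumor_mask(config$grid_shape, config$radius_range,
                                seed = derive_seed(config$seed, paste0("mask", i)))
    truth <- plant_habitats(mask, config$k_true, eff$mixing,
                            seed = derive_seed(config$seed, paste0("habitats", i)))
    ph <- simulate_phases(mask, truth, config$signatures, config$noise_sd,
                          seed = derive_seed(config$seed, paste0("phases", i)),
                          texture_sigma = eff$texture_sigma,
                          background = config$background)
    studies[[i]] <- structure(list(
      patient_id = pid,
      phase_pre = ph$phase_pre, phase_early = ph$phase_early,
      phase_delayed = ph$phase_delayed,
      tumor_mask = mask, spacing = config$spacing,
      her2 = cls, truth_habitats = truth
    ), class = "dce_study")
  }
  if (!is.null(out_dir)) write_cohort(studies, config, out_dir)
  studies
}

#' @export
print.dce_study <- function(x, ...) {
  cat("<dce_study>", x$patient_id, "| HER2-", x$her2,
      "|", sum(x$tumor_mask), "tumor voxels, grid",
      paste(dim(x$tumor_mask), collapse = "x"), "\n")
  invisible(x)
}
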