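# Separable 3-D filtering primitives used by the phantom generator (textured
# noise) and the radiomics filter bank (Laplacian-of-Gaussian, wavelet).

# Reflect (mirror) indices 1..n for out-of-range positions.
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j[j < 0] <- j[j < 0] + p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

# Convolve a 3-D array with a 1-D kernel along one axis, mirror boundary.
# `center` is the 1-based index of the kernel tap aligned with the output voxel.
conv_axis <- function(vol, kernel, axis, center = (length(kernel) + 1L) %/% 2L) {
  d <- dim(vol)
  n <- d[axis]
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    if (kernel[t] == 0) next
    off <- t - center
    src <- reflect_index(seq_len(n) + off, n)
    idx <- switch(axis,
      `1` = list(src, TRUE, TRUE),
      `2` = list(TRUE, src, TRUE),
      `3` = list(TRUE, TRUE, src)
    )
    out <- out + kernel[t] * vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

sep_conv3d <- function(vol, kx, ky, kz) {
  conv_axis(conv_axis(conv_axis(vol, kx, 1L), ky, 2L), kz, 3L)
}

# Normalized Gaussian kernel with sd `sigma` (in physical units) sampled at
# voxel `step`, truncated at 4 sigma.
gauss_kernel <- function(sigma, step = 1) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma / step))
  x <- (-r:r) * step
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis physical spacing.
gaussian_smooth3d <- function(vol, sigma, spacing = c(1, 1, 1)) {
  if (sigma <= 0) return(vol)
  sep_conv3d(vol,
    gauss_kernel(sigma, spacing[1]),
    gauss_kernel(sigma, spacing[2]),
    gauss_kernel(sigma, spacing[3])
  )
}

# Scale-normalized Laplacian of Gaussian: sigma^2 * Laplacian(G_sigma * vol),
# with the Laplacian discretized by central second differences on the
# physical grid. Highlights blob-like structure at scale `sigma` (mm).
log_filter3d <- function(vol, sigma, spacing = c(1, 1, 1)) {
  s <- gaussian_smooth3d(vol, sigma, spacing)
  lap <- array(0, dim(vol))
  for (ax in 1:3) {
    k <- c(1, -2, 1) / spacing[ax]^2
    lap <- lap + conv_axis(s, k, ax)
  }
  sigma^2 * lap
}

# Coiflet-1 analysis filters (orthonormal, 6 taps).
coif1_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  hi <- rev(lo) * c(1, -1, 1, -1, 1, -1)
  list(lo = lo, hi = hi)
}

#' Single-level undecimated 3-D wavelet decomposition
#'
#' Applies the coiflet-1 low-pass (L) / high-pass (H) analysis pair along each
#' axis without downsampling, yielding the eight sub-band images
#' LLL, LLH, ..., HHH at the original grid size so that region masks remain
#' voxel-aligned with the filtered images.
#'
#' @param vol 3-D numeric array.
#' @return Named list of eight arrays (`LLL` ... `HHH`); the sub-band letters
#'   give the filter applied along the x, y and z axes in that order.
#' @export
wavelet_decompose3d <- function(vol) {
  f <- coif1_filters()
  bands <- list()
  for (bx in c("L", "H")) {
    for (by in c("L", "H")) {
      for (bz in c("L", "H")) {
        kx <- if (bx == "L") f$lo else f$hi
        ky <- if (by == "L") f$lo else f$hi
        kz <- if (bz == "L") f$lo else f$hi
        bands[[paste0(bx, by, bz)]] <- sep_conv3d(vol, kx, ky, kz)
      }
    }
  }
  bands
}
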