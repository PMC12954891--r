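# Semiquantitative DCE perfusion parametric maps.
#
# From the three phase volumes S_pre, S_early, S_delayed, the voxel-wise
# parameters are the standard relative-enhancement quantities
#   wash-in          WI  = (S_early - S_pre)    / (S_pre  + eps)
#   wash-out         WO  = (S_delayed - S_early)/ (S_early + eps)
#   wash-out ratio   WOR = (S_early - S_delayed)/(S_early - S_pre)
# WOR is undefined on plateau voxels (|S_early - S_pre| <= eps); those are
# excluded from the valid mask rather than clamped. All three are
# dimensionless and invariant to a common rescaling of the phases.

#' Resample a volume to isotropic spacing
#'
#' Covers the same physical extent on a new grid at `target_spacing`,
#' using the half-open voxel convention (voxel i spans
#' `[(i-1)*s, i*s)`, center at `(i-1/2)*s`). Images are interpolated
#' trilinearly; masks/label volumes with nearest neighbor (and so remain
#' integer-valued).
#'
#' @param volume 3-D array.
#' @param spacing Current per-axis spacing (mm), all > 0.
#' @param target_spacing Desired isotropic spacing (mm, scalar).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return 3-D array with attribute `spacing`.
#' @export
resample_isotropic <- function(volume, spacing, target_spacing = 1,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (any(spacing <= 0) || target_spacing <= 0) stop("spacing must be positive")
  d <- dim(volume)
  extent <- d * spacing
  nd <- pmax(1L, as.integer(ceiling(extent / target_spacing - 1e-9)))
  # physical centers of output voxels -> continuous input voxel coordinates
  ci <- lapply(1:3, function(ax) {
    x <- (seq_len(nd[ax]) - 0.5) * target_spacing
    x / spacing[ax] + 0.5
  })
  if (interpolation == "nearest") {
    ix <- lapply(1:3, function(ax) pmin(pmax(round(ci[[ax]]), 1L), d[ax]))
    out <- volume[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(ax) pmin(pmax(floor(ci[[ax]]), 1L), d[ax]))
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, d[ax]))
    fr <- lapply(1:3, function(ax) pmin(pmax(ci[[ax]] - lo[[ax]], 0), 1))
    out <- array(0, nd)
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      wx <- if (bx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (by == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (bz == 0) 1 - fr[[3]] else fr[[3]]
      sub <- volume[if (bx == 0) lo[[1]] else hi[[1]],
                    if (by == 0) lo[[2]] else hi[[2]],
                    if (bz == 0) lo[[3]] else hi[[3]], drop = FALSE]
      w <- outer(outer(wx, wy), wz)
      out <- out + w * sub
    }
  }
  attr(out, "spacing") <- rep(target_spacing, 3)
  out
}

#' Z-score normalize image intensities within a mask
#'
#' Subtracts the in-mask mean and divides by the in-mask population sd.
#' Voxels outside the mask are set to 0. This normalization feeds the
#' radiomics extraction only; perfusion maps are computed on raw intensities
#' because normalization would destroy the enhancement ratios.
#'
#' @param volume 3-D array.
#' @param mask 3-D 0/1 array (nonempty).
#' @return Normalized 3-D array (in-mask mean 0, sd 1).
#' @export
normalize_intensity <- function(volume, mask) {
  vox <- which(mask != 0)
  if (length(vox) == 0) stop("mask is empty")
  v <- volume[vox]
  s <- pop_sd(v)
  out <- array(0, dim(volume))
  if (!is.finite(s) || s == 0) {
    warning("zero in-mask variance; returning zeros")
    return(out)
  }
  out[vox] <- (v - mean(v)) / s
  out
}

#' Compute wash-in / wash-out / wash-out-ratio parametric maps
#'
#' @param pre,early,delayed Co-registered 3-D phase volumes (identical dims).
#' @param mask 3-D 0/1 tumor mask.
#' @param epsilon Stabilizer added to denominators and used as the plateau
#'   threshold for WOR validity. Default: `1e-6 *` the in-mask median of the
#'   pre-contrast phase.
#' @return A `perfusion_maps` object: `wash_in`, `wash_out`,
#'   `wash_out_ratio` (3-D arrays, `NA` off the valid mask), `valid_mask`,
#'   and `epsilon`.
#' @export
compute_perfusion_maps <- function(pre, early, delayed, mask, epsilon = NULL) {
  if (!all(dim(pre) == dim(early)) || !all(dim(pre) == dim(delayed)) ||
      !all(dim(pre) == dim(mask))) {
    stop("phase volumes and mask must share the same shape")
  }
  vox <- which(mask != 0)
  if (length(vox) == 0) stop("tumor mask is empty")
  if (is.null(epsilon)) epsilon <- 1e-6 * max(median(pre[vox]), 1e-12)
  if (epsilon <= 0) stop("epsilon must be > 0")
  d <- dim(pre)
  wi <- array(NA_real_, d); wo <- array(NA_real_, d); wor <- array(NA_real_, d)
  sp <- pre[vox]; se <- early[vox]; sd_ <- delayed[vox]
  wi_v <- (se - sp) / (sp + epsilon)
  wo_v <- (sd_ - se) / (se + epsilon)
  den <- se - sp
  ok <- abs(den) > epsilon & is.finite(wi_v) & is.finite(wo_v)
  wor_v <- rep(NA_real_, length(vox))
  wor_v[ok] <- (se[ok] - sd_[ok]) / den[ok]
  if (!any(ok)) stop("no voxel has a valid wash-out ratio (all plateau)")
  valid <- array(0L, d); valid[vox[ok]] <- 1L
  wi[vox] <- wi_v; wo[vox] <- wo_v
  wor[vox[ok]] <- wor_v[ok]
  structure(list(
    wash_in = wi, wash_out = wo, wash_out_ratio = wor,
    valid_mask = valid, epsilon = epsilon
  ), class = "perfusion_maps")
}

# Theoretical (WI, WO, WOR) for a kinetic signature in the eps -> 0 limit.
signature_perfusion <- function(signature) {
  sp <- signature$s_pre; se <- signature$s_early; sd_ <- signature$s_delayed
  c(wash_in = (se - sp) / sp,
    wash_out = (sd_ - se) / se,
    wash_out_ratio = if (se != sp) (se - sd_) / (se - sp) else NA_real_)
}
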