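#' Multi-density threshold ladder
#'
#' The ordered set of binarisation thresholds used throughout the analysis.
#' The default ladder runs from 395 to 720 mg HA/cm^3 in steps of 25
#' (14 levels), spanning the range of segmentation thresholds reported for
#' murine bone.
#'
#' @param from,to,by Ladder construction, mg HA/cm^3.
#' @param thresholds Optional explicit vector overriding `from/to/by`.
#' @return Numeric vector of class `threshold_ladder`, strictly increasing.
#' @export
threshold_ladder <- function(from = 395, to = 720, by = 25,
                             thresholds = NULL) {
  tau <- if (is.null(thresholds)) seq(from, to, by) else as.numeric(thresholds)
  if (length(tau) < 1L || any(diff(tau) <= 0))
    stop("thresholds must be strictly increasing")
  structure(tau, class = "threshold_ladder")
}

#' Gaussian noise filter
#'
#' Smooths a density image with a normalised truncated Gaussian kernel
#' (`sigma` in voxels, truncated at `+/- support` voxels, so the default is
#' a 3x3x3 kernel). Applied separably; boundaries are handled by symmetric
#' (reflective) padding. This reproduces the scanner-style sigma 1.2 /
#' support 1 pre-filter.
#'
#' @param image A [density_image()].
#' @param sigma Kernel width in voxels (> 0), default 1.2.
#' @param support Truncation radius in voxels (>= 1), default 1.
#' @return Smoothed [density_image()] (same grid, same frame).
#' @export
gaussian_smooth <- function(image, sigma = 1.2, support = 1) {
  if (sigma <= 0) stop("`sigma` must be positive")
  support <- as.integer(support)
  if (support < 1L) stop("`support` must be >= 1")
  d <- -support:support
  w <- exp(-d^2 / (2 * sigma^2))
  w <- w / sum(w)
  v <- image$values
  for (axis in 1:3) v <- convolve_axis(v, w, axis)
  density_image(v, image$voxel_size, image$frame)
}

# separable 1D convolution along one axis with symmetric padding
convolve_axis <- function(v, w, axis) {
  n <- dim(v)[axis]
  r <- (length(w) - 1L) / 2L
  out <- array(0, dim(v))
  for (k in seq_along(w)) {
    dshift <- k - r - 1L
    src <- seq_len(n) + dshift
    src <- ifelse(src < 1L, 1L - src, ifelse(src > n, 2L * n + 1L - src, src))
    out <- out + w[k] * switch(axis,
                               v[src, , , drop = FALSE],
                               v[, src, , drop = FALSE],
                               v[, , src, drop = FALSE])
  }
  out
}

#' Binarize at one threshold
#'
#' Inclusive comparison: a voxel belongs to the mask when its density is
#' greater than or equal to the threshold.
#'
#' @param image A [density_image()].
#' @param threshold Density threshold, mg HA/cm^3.
#' @return A `binary_mask` (logical 3D array plus threshold and frame).
#' @export
binarize <- function(image, threshold) {
  structure(list(mask = image$values >= threshold,
                 threshold = as.numeric(threshold),
                 frame = image$frame),
            class = "binary_mask")
}

#' Apply the full threshold ladder
#'
#' @param image A [density_image()].
#' @param ladder A [threshold_ladder()].
#' @return A list of `binary_mask`, one per threshold (nested: masks at
#'   higher thresholds are subsets of masks at lower ones).
#' @export
apply_ladder <- function(image, ladder = threshold_ladder()) {
  lapply(as.numeric(ladder), function(tau) binarize(image, tau))
}

#' Translation-only registration
#'
#' Finds the integer voxel offset maximising the normalised
#' cross-correlation between two images of identical shape, via FFT.
#' Convention: `apply_translation(moving, offset)` aligns the moving image
#' to the fixed one (content at position `x` in the result is taken from
#' `x - offset` in the moving image).
#'
#' @param moving,fixed [density_image()] objects on the same grid.
#' @return Integer length-3 offset (voxels).
#' @export
register_translation <- function(moving, fixed) {
  stopifnot_same_grid(moving, fixed)
  f <- fixed$values - mean(fixed$values)
  m <- moving$values - mean(moving$values)
  if (all(f == 0) || all(m == 0))
    stop("cannot register a constant (e.g. all-zero) image")
  cc <- Re(fft(fft(f) * Conj(fft(m)), inverse = TRUE))
  s <- arrayInd(which.max(cc), dim(cc)) - 1L
  n <- dim(cc)
  as.integer(ifelse(s > n / 2, s - n, s))
}

#' Translate an image by an integer voxel offset
#'
#' Content moves by `+offset`; voxels shifted in from outside the grid are
#' zero-filled.
#'
#' @param image A [density_image()].
#' @param offset Integer length-3 offset (voxels).
#' @return Translated [density_image()].
#' @export
apply_translation <- function(image, offset) {
  offset <- as.integer(round(offset))
  d <- dim(image$values)
  out <- array(0, d)
  src_lo <- pmax(1L, 1L - offset)
  src_hi <- pmin(d, d - offset)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo + offset
    dst_hi <- src_hi + offset
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      image$values[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                   src_lo[3]:src_hi[3]]
  }
  density_image(out, image$voxel_size, image$frame)
}

#' Overlay two consecutive binarized images
#'
#' Voxelwise comparison of the bone masks at times t and t+1:
#' formation (`F`) = bone only at t+1, resorption (`R`) = bone only at t,
#' quiescence (`Q`) = bone at both, background (`B`) = bone at neither.
#' Overlays are per-density-level: both masks must share the threshold.
#'
#' @param mask_t,mask_t1 `binary_mask` objects from consecutive frames at
#'   the same threshold.
#' @return An `overlay_labels` object: integer 3D array with codes
#'   B = 0, F = 1, Q = 2, R = 3 plus threshold and frame metadata.
#' @export
overlay <- function(mask_t, mask_t1) {
  if (!identical(dim(mask_t$mask), dim(mask_t1$mask)))
    stop("masks must share the same grid")
  if (!isTRUE(all.equal(mask_t$threshold, mask_t1$threshold)))
    stop(sprintf("overlay requires matching thresholds (got %g and %g)",
                 mask_t$threshold, mask_t1$threshold))
  a <- mask_t$mask
  b <- mask_t1$mask
  lab <- array(.LBL[["B"]], dim(a))
  lab[b & !a] <- .LBL[["F"]]
  lab[a & b] <- .LBL[["Q"]]
  lab[a & !b] <- .LBL[["R"]]
  structure(list(labels = lab, threshold = mask_t$threshold,
                 frames = c(mask_t$frame, mask_t1$frame)),
            class = "overlay_labels")
}

#' Count overlay categories
#'
#' @param ov An `overlay_labels` object.
#' @return Named integer vector with counts of B, F, Q, R voxels.
#' @export
overlay_counts <- function(ov) {
  vapply(.LBL, function(code) sum(ov$labels == code), integer(1))
}
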