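#' Density image
#'
#' The common currency of the pipeline: a 3D scalar field of
#' hydroxyapatite-equivalent mineral density (mg HA/cm^3) on an isotropic
#' voxel grid, with the voxel edge length and the time index (weeks) carried
#' as metadata.
#'
#' @param values 3D numeric array of mineral densities, mg HA/cm^3 (>= 0).
#' @param voxel_size Isotropic voxel edge length in micrometres
#'   (default 10.5, the nominal in vivo scan resolution).
#' @param frame Integer time index of the measurement (weeks post-op).
#' @return An object of class `density_image`.
#' @export
density_image <- function(values, voxel_size = 10.5, frame = 0L) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (anyNA(values) || any(values < 0))
    stop("densities must be non-negative and non-missing")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  structure(list(values = values,
                 voxel_size = as.numeric(voxel_size),
                 frame = as.integer(frame)),
            class = "density_image")
}

#' @export
dim.density_image <- function(x) dim(x$values)

#' @export
print.density_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_image> %d x %d x %d voxels @ %.3g um, frame %d\n",
              d[1], d[2], d[3], x$voxel_size, x$frame))
  cat(sprintf("  density range [%.1f, %.1f] mg HA/cm^3\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# voxel edge in mm
voxel_mm <- function(image) image$voxel_size / 1000

# voxel volume in mm^3
voxel_vol_mm3 <- function(image) (image$voxel_size / 1000)^3

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("images must share the same grid shape")
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("images must share the same voxel size")
  invisible(TRUE)
}
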