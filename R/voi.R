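#' Find the cortical fragments
#'
#' Binarizes the post-operative image at the debris-disconnection threshold
#' (645 mg HA/cm^3), labels connected components and returns the two
#' components that touch the two opposite axial image faces (proximal at
#' z = 1, distal at z = nz). Smaller components (surgical debris) are
#' discarded. A single component spanning both faces means the defect is
#' bridged and cannot be partitioned.
#'
#' @param postop Post-operative [density_image()].
#' @param threshold Debris-disconnection density threshold (default 645).
#' @param connectivity 26 (default) or 6.
#' @return List with logical arrays `proximal` and `distal` and the
#'   labelled integer array `labels`.
#' @export
find_fragments <- function(postop, threshold = 645, connectivity = 26) {
  d <- dim(postop$values)
  mask <- postop$values >= threshold
  lab <- array(.label_components_cpp(as.logical(mask), as.integer(d),
                                     as.integer(connectivity)), d)
  lab_bot <- setdiff(unique(as.vector(lab[, , 1])), 0L)
  lab_top <- setdiff(unique(as.vector(lab[, , d[3]])), 0L)
  both <- intersect(lab_bot, lab_top)
  if (length(both) > 0)
    stop("defect is bridged: a single component spans both axial faces")
  if (length(lab_bot) == 0 || length(lab_top) == 0)
    stop("could not resolve two cortical fragments touching the axial faces")
  pick <- function(cands) {
    sizes <- vapply(cands, function(l) sum(lab == l), integer(1))
    cands[which.max(sizes)]
  }
  lp <- pick(lab_bot)
  ld <- pick(lab_top)
  list(proximal = lab == lp, distal = lab == ld, labels = lab)
}

# hole filling of one 2D slice: pixels not reachable from the border
# through the complement (4-connectivity)
fill_slice <- function(slice) {
  d <- dim(slice)
  comp <- array(.label_components_cpp(as.logical(!slice),
                                      as.integer(c(d, 1L)), 6L), d)
  border <- unique(c(comp[1, ], comp[d[1], ], comp[, 1], comp[, d[2]]))
  border <- setdiff(border, 0L)
  slice | (comp != 0L & !(comp %in% border))
}

#' Fill the marrow cavities
#'
#' Per fragment and per axial slice, flood-fills from outside the slice;
#' interior pixels that cannot be reached (the marrow cavity) are unioned
#' with the cortex, producing the FC volume of interest.
#'
#' @param fragments Output of [find_fragments()].
#' @return Logical 3D array: the FC mask (cortex plus marrow).
#' @export
fill_marrow <- function(fragments) {
  both <- fragments$proximal | fragments$distal
  d <- dim(both)
  fc <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    sl <- both[, , z]
    if (any(sl)) fc[, , z] <- fill_slice(sl)
  }
  fc
}

# signed distance of a 2D shape: negative inside, positive outside (pixels)
signed_distance_2d <- function(shape) {
  if (!any(shape)) stop("empty shape has no signed distance")
  d_out <- .edt2d_cpp(shape)        # distance to nearest shape pixel
  d_in <- .edt2d_cpp(!shape)        # distance to nearest background pixel
  d_out - d_in
}

#' Interpolate the periosteal surface across the gap
#'
#' For each gap slice, produces a 2D cross-section interpolated between the
#' last intact proximal and the first intact distal FC cross-sections, by
#' linear blending of their signed distance maps (thresholded at zero).
#' This is the virtual periosteum used to separate defect periphery from
#' defect centre.
#'
#' @param fc FC mask from [fill_marrow()].
#' @return Logical 3D array: the interpolated (filled) periosteal tube in
#'   the gap slices, FALSE elsewhere. Empty with a warning if there is no
#'   gap.
#' @export
interpolate_periosteum <- function(fc) {
  d <- dim(fc)
  occ <- apply(fc, 3, any)
  out <- array(FALSE, d)
  if (all(occ)) {
    warning("fragments touch: no gap to interpolate")
    return(out)
  }
  gap <- which(!occ)
  # gap must be one contiguous interior run
  if (any(diff(gap) != 1L) || gap[1] == 1L || gap[length(gap)] == d[3])
    stop("gap slices are not a contiguous interior run; cannot interpolate")
  zp <- gap[1] - 1L
  zd <- gap[length(gap)] + 1L
  sd_p <- signed_distance_2d(fc[, , zp])
  sd_d <- signed_distance_2d(fc[, , zd])
  G <- length(gap)
  for (i in seq_len(G)) {
    t <- if (G == 1L) 0.5 else (i - 1) / (G - 1)
    out[, , gap[i]] <- ((1 - t) * sd_p + t * sd_d) < 0
  }
  out
}

#' Ray-cast partition into the four volumes of interest
#'
#' Casts rays from the four transverse image boundaries along the in-plane
#' axes (perpendicular to the fragment axis). Voxels between the boundary
#' and the first struck surface join the fragment periphery (FP) when the
#' strike is cortical/marrow material (FC) and the defect periphery (DP)
#' when it is the virtual periosteum; where FP and DP claims overlap, FP
#' wins. The defect centre (DC) is the complement of FC, FP and DP, so the
#' four masks partition the image exactly.
#'
#' @param fc FC mask from [fill_marrow()].
#' @param virtual Virtual periosteum from [interpolate_periosteum()].
#' @param voxel_size Voxel edge, micrometres (for the TV constants).
#' @return An object of class `voi_set`: logical masks `DC`, `DP`, `FC`,
#'   `FP` plus `TV_defect` and `TV_fragment` in mm^3.
#' @export
raycast_partition <- function(fc, virtual, voxel_size) {
  d <- dim(fc)
  fp <- array(FALSE, d)
  dp <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    sfc <- fc[, , z]
    svt <- virtual[, , z]
    hit <- sfc | svt
    if (!any(hit)) next
    fp_s <- matrix(FALSE, d[1], d[2])
    dp_s <- matrix(FALSE, d[1], d[2])
    cast <- function(H) {
      # H: logical matrix rows = along-ray coordinate; returns list of
      # (before-first-hit mask, hit-is-fc mask per column)
      n <- nrow(H)
      anyhit <- colSums(H) > 0
      first <- max.col(t(H) * 1L, ties.method = "first")
      before <- outer(seq_len(n), first, "<") & rep(anyhit, each = n)
      list(before = before, first = first, anyhit = anyhit)
    }
    assign_dir <- function(hit_m, fc_m, flip, transpose) {
      H <- hit_m; Fm <- fc_m
      if (transpose) { H <- t(H); Fm <- t(Fm) }
      if (flip) { H <- H[rev(seq_len(nrow(H))), , drop = FALSE]
                  Fm <- Fm[rev(seq_len(nrow(Fm))), , drop = FALSE] }
      cs <- cast(H)
      hit_fc <- rep(FALSE, ncol(H))
      hit_fc[cs$anyhit] <- Fm[cbind(cs$first[cs$anyhit],
                                    which(cs$anyhit))]
      fp_b <- cs$before & rep(hit_fc, each = nrow(H))
      dp_b <- cs$before & !rep(hit_fc, each = nrow(H))
      if (flip) { fp_b <- fp_b[rev(seq_len(nrow(fp_b))), , drop = FALSE]
                  dp_b <- dp_b[rev(seq_len(nrow(dp_b))), , drop = FALSE] }
      if (transpose) { fp_b <- t(fp_b); dp_b <- t(dp_b) }
      fp_s <<- fp_s | fp_b
      dp_s <<- dp_s | dp_b
    }
    assign_dir(hit, sfc, flip = FALSE, transpose = FALSE)  # from x = 1
    assign_dir(hit, sfc, flip = TRUE, transpose = FALSE)   # from x = nx
    assign_dir(hit, sfc, flip = FALSE, transpose = TRUE)   # from y = 1
    assign_dir(hit, sfc, flip = TRUE, transpose = TRUE)    # from y = ny
    fp_s <- fp_s & !sfc & !svt
    dp_s <- dp_s & !sfc & !svt & !fp_s
    fp[, , z] <- fp_s
    dp[, , z] <- dp_s
  }
  dc <- !(fc | fp | dp)
  vol <- (voxel_size / 1000)^3
  structure(list(DC = dc, DP = dp, FC = fc, FP = fp,
                 TV_defect = sum(dc) * vol, TV_fragment = sum(fc) * vol,
                 voxel_size = voxel_size),
            class = "voi_set")
}

#' Automatic VOI definition
#'
#' Convenience wrapper: [find_fragments()], [fill_marrow()],
#' [interpolate_periosteum()] and [raycast_partition()] in sequence.
#'
#' @param postop Post-operative [density_image()].
#' @param threshold Debris-disconnection threshold (default 645).
#' @param connectivity Component connectivity (default 26).
#' @return A `voi_set`.
#' @export
define_vois <- function(postop, threshold = 645, connectivity = 26) {
  fr <- find_fragments(postop, threshold, connectivity)
  fc <- fill_marrow(fr)
  virt <- interpolate_periosteum(fc)
  raycast_partition(fc, virt, postop$voxel_size)
}

#' @export
print.voi_set <- function(x, ...) {
  cat(sprintf("<voi_set> DC %d | DP %d | FC %d | FP %d voxels\n",
              sum(x$DC), sum(x$DP), sum(x$FC), sum(x$FP)))
  cat(sprintf("  TV_defect %.4g mm^3, TV_fragment %.4g mm^3\n",
              x$TV_defect, x$TV_fragment))
  invisible(x)
}
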