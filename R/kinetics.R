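#' Bone volume time course per VOI and threshold
#'
#' Tabulates BV and BV/TV for every frame, density threshold and volume of
#' interest. The reference volume (TV) is the defect-centre volume for DC
#' and DP and the fragment volume for FC and FP, i.e. the intact-bone
#' volume that healing aims to restore.
#'
#' @param mask_series List over frames of lists over thresholds of
#'   `binary_mask` (as from [apply_ladder()] per frame).
#' @param vois A `voi_set`.
#' @return `data.frame` with columns frame, threshold, voi, BV (mm^3),
#'   TV (mm^3), BVTV.
#' @export
bvtv_timecourse <- function(mask_series, vois) {
  voi_masks <- list(DC = vois$DC, DP = vois$DP, FC = vois$FC, FP = vois$FP)
  tvs <- c(DC = vois$TV_defect, DP = vois$TV_defect,
           FC = vois$TV_fragment, FP = vois$TV_fragment)
  vol <- (vois$voxel_size / 1000)^3
  rows <- list()
  for (masks in mask_series) {
    for (bm in masks) {
      for (v in names(voi_masks)) {
        bv <- sum(bm$mask & voi_masks[[v]]) * vol
        rows[[length(rows) + 1L]] <-
          data.frame(frame = bm$frame, threshold = bm$threshold, voi = v,
                     BV = bv, TV = tvs[[v]], BVTV = bv / tvs[[v]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Remodelling rates per VOI and threshold
#'
#' Formed and resorbed volume per week from consecutive-frame overlays,
#' reported both as absolute mm^3 per week and as a fraction of the
#' reference TV per week. The conservation identity
#' `BV(t+1) = BV(t) + formed - resorbed` holds exactly per threshold and
#' VOI.
#'
#' @param overlay_series List of `overlay_labels` (any frames/thresholds).
#' @param vois A `voi_set`.
#' @return `data.frame` with columns frame_from, frame_to, threshold, voi,
#'   formed_mm3, resorbed_mm3, formed_rate, resorbed_rate (TV fraction per
#'   week).
#' @export
remodelling_rates <- function(overlay_series, vois) {
  voi_masks <- list(DC = vois$DC, DP = vois$DP, FC = vois$FC, FP = vois$FP)
  tvs <- c(DC = vois$TV_defect, DP = vois$TV_defect,
           FC = vois$TV_fragment, FP = vois$TV_fragment)
  vol <- (vois$voxel_size / 1000)^3
  rows <- list()
  for (ov in overlay_series) {
    for (v in names(voi_masks)) {
      f <- sum(ov$labels == .LBL[["F"]] & voi_masks[[v]]) * vol
      r <- sum(ov$labels == .LBL[["R"]] & voi_masks[[v]]) * vol
      rows[[length(rows) + 1L]] <-
        data.frame(frame_from = ov$frames[1], frame_to = ov$frames[2],
                   threshold = ov$threshold, voi = v,
                   formed_mm3 = f, resorbed_mm3 = r,
                   formed_rate = f / tvs[[v]], resorbed_rate = r / tvs[[v]])
    }
  }
  do.call(rbind, rows)
}
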