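#' ROC association between strain and mineralisation
#'
#' Treats every voxel that is non-bone at time t inside the volume of
#' interest as a candidate: condition positive if it is mineralised at
#' t+1 (formation), condition negative otherwise. The preceding effective
#' strain is swept as a classification threshold (`signal > threshold`
#' predicts mineralisation), giving the ROC curve; AUC by the trapezoid
#' rule and the optimal operating point as the point furthest from the 45
#' degree random-classifier line (argmax of Youden's J = TPR - FPR, ties
#' resolved towards the lowest threshold).
#'
#' @param strain `strain_field` (or 3D effective-strain array) at time t.
#' @param labels `overlay_labels` for the pair t -> t+1.
#' @param voi_mask Logical 3D array restricting the candidate set
#'   (typically DC | DP); NULL for the whole image.
#' @return An object of class `roc_result`: `fpr`, `tpr`, `thresholds`
#'   (curve from (0,0) to (1,1)), `auc`, `T_opt`, `tpr_opt`, `fpr_opt`,
#'   `n_pos`, `n_neg`, plus threshold/frame metadata.
#' @export
roc_analysis <- function(strain, labels, voi_mask = NULL) {
  eps <- if (inherits(strain, "strain_field")) strain$eff_strain else strain
  if (!identical(dim(eps), dim(labels$labels)))
    stop("strain field and labels must share the grid")
  cand <- labels$labels == .LBL[["F"]] | labels$labels == .LBL[["B"]]
  if (!is.null(voi_mask)) cand <- cand & voi_mask
  truth <- labels$labels[cand] == .LBL[["F"]]
  s <- eps[cand]
  roc_from_samples(s, truth, threshold = labels$threshold,
                   frames = labels$frames)
}

# core ROC sweep on raw samples
roc_from_samples <- function(s, truth, threshold = NA_real_, frames = NULL) {
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("ROC undefined: %d positives, %d negatives", n_pos, n_neg))
  o <- order(s, decreasing = TRUE)
  s_o <- s[o]
  t_o <- truth[o]
  tp <- cumsum(t_o)
  fp <- cumsum(!t_o)
  # collapse ties: keep the last entry of each distinct value block
  last <- c(s_o[-1] != s_o[-length(s_o)], TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, s_o[last])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 T_opt = thr[best], tpr_opt = tpr[best], fpr_opt = fpr[best],
                 n_pos = n_pos, n_neg = n_neg,
                 threshold = threshold, frames = frames),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f, T_opt %.4g (TPR %.3f, FPR %.3f), %d+/%d-\n",
              x$auc, x$T_opt, x$tpr_opt, x$fpr_opt, x$n_pos, x$n_neg))
  invisible(x)
}

#' Extract bone-surface remodelling states
#'
#' The bone surface at time t is found with a von Neumann (6-connected,
#' radius 1) neighbourhood on the overlay labels. Ground-truth states:
#' formation = quiescent-bone voxel with a newly formed face neighbour;
#' resorption = resorbed voxel with a background face neighbour;
#' quiescence = quiescent-bone voxel with a background face neighbour and
#' no formation neighbour (formation takes precedence). The signal is the
#' preceding effective strain sampled at the surface voxel itself.
#'
#' @param labels `overlay_labels` for the pair t -> t+1.
#' @param strain `strain_field` (or 3D array) at time t; optional, may be
#'   NULL if only states are needed.
#' @return An object of class `surface_state_map`: voxel `index`, factor
#'   `state` with levels F, Q, R, and `signal` (NULL if no strain given).
#' @export
extract_surface_states <- function(labels, strain = NULL) {
  lab <- labels$labels
  Fm <- lab == .LBL[["F"]]
  Qm <- lab == .LBL[["Q"]]
  Rm <- lab == .LBL[["R"]]
  Bm <- lab == .LBL[["B"]]
  if (!any(Qm | Rm)) warning("no bone at time t: empty surface map")
  form <- face_adjacent(Qm, Fm)
  res <- face_adjacent(Rm, Bm)
  qui <- face_adjacent(Qm, Bm) & !form
  idx <- c(which(form), which(qui), which(res))
  state <- factor(rep(c("F", "Q", "R"),
                      c(sum(form), sum(qui), sum(res))),
                  levels = c("F", "Q", "R"))
  sig <- NULL
  if (!is.null(strain)) {
    eps <- if (inherits(strain, "strain_field")) strain$eff_strain else strain
    if (!identical(dim(eps), dim(lab)))
      stop("strain field and labels must share the grid")
    sig <- eps[idx]
  }
  structure(list(index = idx, state = state, signal = sig,
                 threshold = labels$threshold, frames = labels$frames),
            class = "surface_state_map")
}

#' Two-threshold mechanostat classifier
#'
#' Predicts the remodelling state from the surface signal: above the
#' formation threshold `T_F` formation, below the resorption threshold
#' `T_R` resorption, otherwise (closed interval, including the boundary
#' values) quiescence. `T_R` must lie below `T_F`.
#'
#' @param signal Numeric vector of surface signals (effective strain).
#' @param T_R,T_F Resorption and formation thresholds.
#' @return Factor with levels F, Q, R.
#' @export
classify_surface <- function(signal, T_R, T_F) {
  if (T_R >= T_F) stop("`T_R` must be below `T_F` (thresholds cannot overlap)")
  out <- rep("Q", length(signal))
  out[signal > T_F] <- "F"
  out[signal < T_R] <- "R"
  factor(out, levels = c("F", "Q", "R"))
}

#' Category-normalised confusion matrix and CCR
#'
#' `C[i, j]` is the fraction of voxels of true category j predicted as i
#' (columns sum to one for nonempty truth categories), so each remodelling
#' event type carries equal weight regardless of its abundance. The correct
#' classification rate is the mean diagonal, `CCR = trace(C) / 3`; empty
#' truth categories contribute zero to the trace and are flagged.
#'
#' @param predicted,truth Factors with levels F, Q, R on the same voxels.
#' @return An object of class `confusion_ccr`: `C` (3x3), `ccr`,
#'   `empty_categories`.
#' @export
confusion_ccr <- function(predicted, truth) {
  lv <- c("F", "Q", "R")
  predicted <- factor(predicted, levels = lv)
  truth <- factor(truth, levels = lv)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  counts <- table(predicted, truth)
  coln <- colSums(counts)
  if (all(coln == 0)) stop("all truth categories are empty")
  C <- sweep(unclass(counts), 2, pmax(coln, 1L), "/")
  empty <- lv[coln == 0]
  C[, coln == 0] <- 0
  ccr <- sum(diag(C)) / 3
  structure(list(C = C, ccr = ccr, empty_categories = empty),
            class = "confusion_ccr")
}

#' @export
print.confusion_ccr <- function(x, ...) {
  cat(sprintf("<confusion_ccr> CCR %.4f", x$ccr))
  if (length(x$empty_categories))
    cat(sprintf(" (empty: %s)", paste(x$empty_categories, collapse = ", ")))
  cat("\n")
  print(round(x$C, 3))
  invisible(x)
}

#' CCR heat map over the threshold plane
#'
#' Sweeps the threshold pair (T_R, T_F) over a grid spanning the signal
#' range (quantile-spaced by default) and evaluates the CCR at every
#' admissible pair (T_R < T_F, the lower triangle). Records the maximum and
#' its argmax (ties resolved to the lexicographically smallest pair).
#'
#' @param map `surface_state_map` with signals.
#' @param grid Either a single integer (number of quantile-spaced
#'   thresholds, default 64) or an explicit numeric vector of thresholds.
#' @return An object of class `remodel_heatmap`: `ccr` matrix (rows = T_R,
#'   cols = T_F, NA where T_R >= T_F), `thresholds`, `max_ccr`, `T_R_opt`,
#'   `T_F_opt`, metadata.
#' @export
ccr_heatmap <- function(map, grid = 64) {
  if (is.null(map$signal)) stop("surface map carries no signal")
  s <- map$signal
  g <- map$state
  if (length(grid) == 1L) {
    thr <- unique(quantile(s, probs = seq(0, 1, length.out = as.integer(grid)),
                           names = FALSE, type = 7))
  } else {
    thr <- sort(unique(as.numeric(grid)))
  }
  n <- length(thr)
  lv <- c("F", "Q", "R")
  ntr <- vapply(lv, function(l) sum(g == l), integer(1))
  # per category, counts strictly below / at-or-below each grid threshold
  below <- sapply(lv, function(l) {
    sl <- s[g == l]
    vapply(thr, function(t) sum(sl < t), numeric(1))
  })
  at_or_below <- sapply(lv, function(l) {
    sl <- s[g == l]
    vapply(thr, function(t) sum(sl <= t), numeric(1))
  })
  ccr <- matrix(NA_real_, n, n, dimnames = list(T_R = NULL, T_F = NULL))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (thr[i] >= thr[j]) next
      # predicted R: s < T_R; predicted F: s > T_F; Q: closed interval
      cRR <- if (ntr["R"] > 0) below[i, "R"] / ntr["R"] else 0
      cFF <- if (ntr["F"] > 0) (ntr["F"] - at_or_below[j, "F"]) / ntr["F"] else 0
      cQQ <- if (ntr["Q"] > 0)
        (at_or_below[j, "Q"] - below[i, "Q"]) / ntr["Q"] else 0
      ccr[i, j] <- (cRR + cFF + cQQ) / 3
    }
  }
  best <- which(ccr == max(ccr, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(ccr = ccr, thresholds = thr,
                 max_ccr = ccr[best[1], best[2]],
                 T_R_opt = thr[best[1]], T_F_opt = thr[best[2]],
                 threshold = map$threshold, frames = map$frames),
            class = "remodel_heatmap")
}

#' @export
print.remodel_heatmap <- function(x, ...) {
  cat(sprintf("<remodel_heatmap> %d thresholds, max CCR %.4f at (T_R %.4g, T_F %.4g)\n",
              length(x$thresholds), x$max_ccr, x$T_R_opt, x$T_F_opt))
  invisible(x)
}
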