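make_labels <- function(dim3, f_idx, q_idx, r_idx, tau = 395) {
  lab <- array(0L, dim3)
  lab[f_idx] <- 1L
  lab[q_idx] <- 2L
  lab[r_idx] <- 3L
  structure(list(labels = lab, threshold = tau, frames = c(0L, 1L)),
            class = "overlay_labels")
}

test_that("ROC handles perfect separation and degenerate inputs", {
  d <- c(10, 10, 10)
  s <- array(runif(1000, 0, 0.2), d)
  f_idx <- 1:50
  s[f_idx] <- runif(50, 0.5, 1)
  lab <- make_labels(d, f_idx, integer(), integer())
  roc <- roc_analysis(s, lab)
  expect_equal(roc$auc, 1)
  expect_equal(roc$tpr_opt, 1)
  expect_equal(roc$fpr_opt, 0)
  # curve anchored at (0,0) and (1,1), monotone
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # no positives -> explicit failure
  expect_error(roc_analysis(s, make_labels(d, integer(), 1:10, integer())),
               "positives")
})

test_that("sweep AUC equals the Mann-Whitney pair-count oracle", {
  set.seed(14)
  n <- 2000
  truth <- runif(n) < 0.3
  # mixture with heavy ties to stress the tie handling
  s <- round(rnorm(n, mean = ifelse(truth, 0.8, 0.2), sd = 0.5), 1)
  roc <- mechanoct:::roc_from_samples(s, truth)
  expect_equal(roc$auc, oracle_mw_auc(s, truth), tolerance = 1e-12)
  # continuous signals too
  s2 <- rnorm(n, ifelse(truth, 1, 0))
  roc2 <- mechanoct:::roc_from_samples(s2, truth)
  expect_equal(roc2$auc, oracle_mw_auc(s2, truth), tolerance = 1e-12)
})

test_that("labels independent of strain give a near-0.5 AUC", {
  set.seed(15)
  n <- 2000
  s <- runif(n)
  truth <- runif(n) < 0.5
  roc <- mechanoct:::roc_from_samples(s, truth)
  expect_gt(roc$auc, 0.45)
  expect_lt(roc$auc, 0.55)
})

test_that("AUC is invariant under strictly monotone signal transforms", {
  set.seed(16)
  n <- 500
  truth <- runif(n) < 0.4
  s <- rnorm(n, ifelse(truth, 0.6, 0))
  a0 <- mechanoct:::roc_from_samples(s, truth)$auc
  expect_equal(mechanoct:::roc_from_samples(exp(s), truth)$auc, a0,
               tolerance = 1e-12)
  expect_equal(mechanoct:::roc_from_samples(3 * s + 7, truth)$auc, a0,
               tolerance = 1e-12)
})

test_that("surface states follow the interface definitions", {
  d <- c(5, 5, 5)
  # isolated quiescent voxel surrounded by background -> quiescence
  lab <- make_labels(d, integer(), 63L, integer())  # centre voxel (3,3,3)
  m <- extract_surface_states(lab)
  expect_identical(m$index, 63L)
  expect_identical(as.character(m$state), "Q")
  # isolated resorbed voxel -> resorption
  m2 <- extract_surface_states(make_labels(d, integer(), integer(), 63L))
  expect_identical(as.character(m2$state), "R")
  # quiescent voxel with both formed and background neighbours -> formation
  m3 <- extract_surface_states(make_labels(d, 64L, 63L, integer()))
  st3 <- as.character(m3$state[m3$index == 63L])
  expect_identical(st3, "F")
  # no bone at all -> empty map with warning
  expect_warning(m4 <- extract_surface_states(make_labels(d, 1L, integer(),
                                                          integer())),
                 "no bone")
  expect_length(m4$index, 0L)
})

test_that("two-threshold classifier follows the mechanostat branches", {
  expect_identical(as.character(classify_surface(0.5, 0.2, 0.8)), "Q")
  expect_identical(as.character(classify_surface(0.9, 0.2, 0.8)), "F")
  expect_identical(as.character(classify_surface(0.1, 0.2, 0.8)), "R")
  # boundary values belong to the closed quiescent interval
  expect_identical(as.character(classify_surface(c(0.2, 0.8), 0.2, 0.8)),
                   c("Q", "Q"))
  # degenerate limits
  expect_true(all(classify_surface(runif(20), -Inf, Inf) == "Q"))
  s <- runif(20, 0.5, 1)
  expect_true(all(classify_surface(s, 0, 0.4) == "F"))
  expect_error(classify_surface(0.5, 0.8, 0.2), "overlap")
})

test_that("confusion matrix is category-normalised and CCR averaged", {
  truth <- factor(rep(c("F", "Q", "R"), c(10, 30, 5)), c("F", "Q", "R"))
  perfect <- confusion_ccr(truth, truth)
  expect_equal(unname(perfect$C), diag(3))
  expect_equal(perfect$ccr, 1)
  # constant quiescence prediction: CCR 1/3 regardless of imbalance
  const <- confusion_ccr(factor(rep("Q", 45), c("F", "Q", "R")), truth)
  expect_equal(const$ccr, 1 / 3)
  # duplication invariance (the equal-weighting property)
  set.seed(17)
  pred <- factor(sample(c("F", "Q", "R"), 45, TRUE), c("F", "Q", "R"))
  c1 <- confusion_ccr(pred, truth)
  c2 <- confusion_ccr(rep(pred, 2), rep(truth, 2))
  expect_equal(c1$C, c2$C)
  expect_equal(c1$ccr, c2$ccr)
  # random prediction: expected CCR 1/3, binomial 3 sigma bound at n = 1e4
  truth_big <- factor(sample(c("F", "Q", "R"), 1e4, TRUE), c("F", "Q", "R"))
  pred_big <- factor(sample(c("F", "Q", "R"), 1e4, TRUE), c("F", "Q", "R"))
  ccr <- confusion_ccr(pred_big, truth_big)$ccr
  expect_lt(abs(ccr - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 1e4))
  # empty categories flagged, all-empty rejected
  t2 <- factor(rep("Q", 5), c("F", "Q", "R"))
  cc <- confusion_ccr(t2, t2)
  expect_setequal(cc$empty_categories, c("F", "R"))
  expect_equal(cc$ccr, 1 / 3)
})

test_that("CCR heat map recovers a realisable threshold pair exactly", {
  set.seed(18)
  n <- 400
  s <- runif(n)
  true_pair <- c(0.3, 0.7)
  state <- factor(ifelse(s > 0.7, "F", ifelse(s < 0.3, "R", "Q")),
                  c("F", "Q", "R"))
  map <- structure(list(index = seq_len(n), state = state, signal = s,
                        threshold = 395, frames = c(0L, 1L)),
                   class = "surface_state_map")
  # grid spanning the signal range and bracketing the true pair
  grid <- sort(unique(c(seq(0, 1, length.out = 30), true_pair)))
  hm <- ccr_heatmap(map, grid = grid)
  expect_equal(hm$max_ccr, 1)
  # the argmax pair must classify perfectly, hence bracket the true pair
  pred <- classify_surface(s, hm$T_R_opt, hm$T_F_opt)
  expect_identical(as.character(pred), as.character(state))
  # lower-triangle domain only
  nthr <- length(hm$thresholds)
  for (i in seq_len(nthr)) for (j in seq_len(nthr))
    if (hm$thresholds[i] >= hm$thresholds[j])
      expect_true(is.na(hm$ccr[i, j]))
})

test_that("heat map equals the exhaustive double-loop oracle", {
  set.seed(19)
  n <- 300
  s <- rnorm(n)
  state <- factor(sample(c("F", "Q", "R"), n, TRUE, prob = c(.3, .5, .2)),
                  c("F", "Q", "R"))
  map <- structure(list(index = seq_len(n), state = state, signal = s,
                        threshold = 395, frames = c(0L, 1L)),
                   class = "surface_state_map")
  thr <- as.numeric(quantile(s, seq(0, 1, length.out = 16), names = FALSE))
  hm <- ccr_heatmap(map, grid = thr)
  or <- oracle_ccr_sweep(s, state, sort(unique(thr)))
  expect_equal(hm$max_ccr, or$max, tolerance = 1e-12)
  expect_equal(hm$T_R_opt, or$T_R)
  expect_equal(hm$T_F_opt, or$T_F)
})
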