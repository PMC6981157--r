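test_that("threshold ladder construction and validation", {
  lad <- threshold_ladder()
  expect_length(lad, 14L)
  expect_true(all(c(395, 720) %in% as.numeric(lad)))
  expect_true(all(diff(as.numeric(lad)) == 25))
  expect_error(threshold_ladder(thresholds = c(500, 400)), "increasing")
})

test_that("gaussian filter is normalised, mass preserving and validated", {
  img <- density_image(array(123.4, c(8, 8, 8)), 20)
  sm <- gaussian_smooth(img)
  expect_equal(sm$values, img$values, tolerance = 1e-12)

  # impulse response: centre weight recomputed from the kernel definition
  v <- array(0, c(9, 9, 9))
  v[5, 5, 5] <- 1
  sm2 <- gaussian_smooth(density_image(v, 20), sigma = 1.2, support = 1)
  g1 <- exp(-(-1:1)^2 / (2 * 1.2^2))
  w <- outer(outer(g1, g1), g1)
  w <- w / sum(w)
  expect_equal(sm2$values[5, 5, 5], w[2, 2, 2], tolerance = 1e-12)
  expect_equal(sm2$values[4, 5, 6], w[1, 2, 3], tolerance = 1e-12)

  # interior mass preservation: pad so nothing reaches the boundary
  set.seed(1)
  v3 <- array(0, c(10, 10, 10))
  v3[3:8, 3:8, 3:8] <- runif(216)
  sm3 <- gaussian_smooth(density_image(v3, 20))
  expect_equal(sum(sm3$values), sum(v3), tolerance = 1e-12)

  expect_error(gaussian_smooth(img, sigma = 0), "sigma")
  expect_error(gaussian_smooth(img, support = 0), "support")
})

test_that("ladder masks are nested and thresholds inclusive", {
  set.seed(2)
  img <- density_image(array(runif(20^3, 0, 900), c(20, 20, 20)), 20)
  img$values[1, 1, 1] <- 400
  masks <- apply_ladder(img)
  expect_length(masks, 14L)
  # a 400-density voxel appears only in the 395 mask
  in_mask <- vapply(masks, function(m) m$mask[1, 1, 1], logical(1))
  expect_identical(in_mask, c(TRUE, rep(FALSE, 13)))
  # exact threshold value is included (inclusive comparison)
  img$values[2, 2, 2] <- 420
  expect_true(apply_ladder(img)[[2]]$mask[2, 2, 2])
  # nesting: higher-threshold masks are subsets of lower ones
  for (k in 2:14)
    expect_true(all(masks[[k]]$mask <= masks[[k - 1]]$mask))
})

test_that("translation registration recovers integer offsets", {
  set.seed(9)
  v <- array(0, c(24, 24, 24))
  v[8:16, 8:16, 6:18] <- runif(9 * 9 * 13, 200, 900)
  fixed <- density_image(v, 20)
  off <- c(2L, -1L, 3L)
  moving <- apply_translation(fixed, off)   # content moved by +off
  est <- register_translation(moving, fixed)
  expect_identical(est, -off)
  expect_identical(register_translation(fixed, fixed), c(0L, 0L, 0L))
  # inverse consistency
  expect_identical(register_translation(fixed, moving), off)
  # applying the estimated offset aligns the images
  expect_equal(apply_translation(moving, est)$values[5:20, 5:20, 5:20],
               fixed$values[5:20, 5:20, 5:20])
  expect_error(register_translation(density_image(array(0, c(24, 24, 24)), 20),
                                    fixed),
               "constant")
})

test_that("noisy registration matches a brute-force correlation sweep", {
  set.seed(10)
  v <- array(runif(16^3, 0, 100), c(16, 16, 16))
  v[5:12, 5:12, 5:12] <- v[5:12, 5:12, 5:12] + 500
  fixed <- density_image(v, 20)
  moving <- apply_translation(fixed, c(1L, 0L, -2L))
  # additive noise at roughly SNR 10
  moving$values <- moving$values + rnorm(16^3, 0, sd(v) / 10)
  moving$values[moving$values < 0] <- 0
  est <- register_translation(moving, fixed)
  # independent oracle: exhaustive normalised correlation over +/-3
  best <- NULL
  for (sx in -3:3) for (sy in -3:3) for (sz in -3:3) {
    shifted <- apply_translation(moving, c(sx, sy, sz))$values
    cc <- suppressWarnings(cor(as.vector(shifted), as.vector(fixed$values)))
    if (is.null(best) || cc > best$cc) best <- list(cc = cc, s = c(sx, sy, sz))
  }
  expect_identical(est, as.integer(best$s))
  expect_identical(est, c(-1L, 0L, 2L))
})

test_that("overlay encodes formation/quiescence/resorption correctly", {
  a <- array(FALSE, c(4, 4, 4))
  b <- a
  a[2, 2, 2] <- TRUE   # resorbed
  a[3, 3, 3] <- TRUE; b[3, 3, 3] <- TRUE  # quiescent
  b[1, 1, 1] <- TRUE   # formed
  mt <- list(mask = a, threshold = 395, frame = 0L)
  mt1 <- list(mask = b, threshold = 395, frame = 1L)
  ov <- overlay(structure(mt, class = "binary_mask"),
                structure(mt1, class = "binary_mask"))
  expect_equal(ov$labels[2, 2, 2], 3)  # R: bone at t, background at t+1
  expect_equal(ov$labels[3, 3, 3], 2)  # Q
  expect_equal(ov$labels[1, 1, 1], 1)  # F
  cnt <- overlay_counts(ov)
  expect_equal(unname(cnt[["F"]] + cnt[["Q"]]), sum(b))
  expect_equal(unname(cnt[["R"]] + cnt[["Q"]]), sum(a))
  # identical masks: no F, no R
  ov2 <- overlay(structure(mt, class = "binary_mask"),
                 structure(list(mask = a, threshold = 395, frame = 1L),
                           class = "binary_mask"))
  expect_equal(unname(overlay_counts(ov2)[c("F", "R")]), c(0L, 0L))
  expect_error(overlay(structure(mt, class = "binary_mask"),
                       structure(list(mask = b, threshold = 420, frame = 1L),
                                 class = "binary_mask")),
               "threshold")
})

test_that("overlay conservation holds across a simulated series", {
  sim <- accept_sim()
  taus <- c(395, 545, 720)
  for (tau in taus) {
    for (t in 1:2) {
      m0 <- binarize(sim$series[[t]], tau)
      m1 <- binarize(sim$series[[t + 1]], tau)
      cnt <- overlay_counts(overlay(m0, m1))
      expect_identical(cnt[["F"]] + cnt[["Q"]], sum(m1$mask))
      expect_identical(cnt[["R"]] + cnt[["Q"]], sum(m0$mask))
    }
  }
})
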