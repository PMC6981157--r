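test_that("phantom geometry and rasterisation follow the stated defect", {
  # 0.85 mm at 10.5 um -> 81 axial slices (round(850 / 10.5))
  g <- phantom_geometry(grid_shape = c(24L, 24L, 100L), voxel_size = 10.5,
                        outer_major_axis = 0.2, outer_minor_axis = 0.14,
                        cortical_thickness = 0.05, gap_length = 0.85)
  expect_identical(g$gap_vox, 81L)
  ph <- build_phantom(g)
  sl <- mechanoct:::phantom_fragment_slices(g)
  expect_length(sl$gap, 81L)
  # all gap slices empty, all other voxels either 0 or cortical density
  expect_true(all(ph$values[, , sl$gap] == 0))
  expect_setequal(unique(as.vector(ph$values)), c(0, g$cortical_density))
  # fragments touch the two axial faces
  expect_gt(sum(ph$values[, , 1]), 0)
  expect_gt(sum(ph$values[, , 100]), 0)
})

test_that("geometry validation fails with the offending dimension", {
  expect_error(phantom_geometry(grid_shape = c(16L, 16L, 32L),
                                voxel_size = 10.5, outer_major_axis = 2),
               "outer_major_axis")
  expect_error(phantom_geometry(gap_length = 0), "gap_length")
  expect_error(phantom_geometry(grid_shape = c(48L, 48L, 40L),
                                voxel_size = 20, gap_length = 0.85),
               "gap_length")
  expect_error(phantom_geometry(cortical_density = 700), "cortical_density")
})

test_that("degenerate thickness gives a solid section with no marrow", {
  g <- phantom_geometry(grid_shape = c(20L, 20L, 20L), voxel_size = 40,
                        outer_major_axis = 0.6, outer_minor_axis = 0.4,
                        cortical_thickness = 0.2, gap_length = 0.2)
  sec <- mechanoct:::phantom_sections(g)
  expect_equal(sum(sec$marrow), 0)
  expect_identical(sec$cortex, sec$outer)
})

test_that("rasterised fragment volume approaches the analytic volume", {
  g <- phantom_geometry(grid_shape = c(96L, 96L, 64L), voxel_size = 10.5,
                        outer_major_axis = 0.8, outer_minor_axis = 0.4,
                        cortical_thickness = 0.1, gap_length = 0.2)
  ph <- build_phantom(g)
  h <- 10.5 / 1000
  a <- 0.4; b <- 0.2; ai <- 0.3; bi <- 0.1
  n_frag <- sum(ph$values > 0)
  frag_len <- (64L - g$gap_vox) * h
  analytic <- pi * (a * b - ai * bi) * frag_len
  expect_equal(n_frag * h^3, analytic, tolerance = 0.05)
})

test_that("image noise is clipped, unbiased and reproducible", {
  img <- density_image(array(900, c(100, 100, 100)), 20)
  expect_identical(add_image_noise(img, 0), img)
  n1 <- add_image_noise(img, 25, rng_seed = 5)
  n2 <- add_image_noise(img, 25, rng_seed = 5)
  expect_identical(n1$values, n2$values)
  # CLT bound: mean shift below 3 sigma / sqrt(n) on 1e6 voxels (no clipping
  # at density 900 with sigma 25)
  expect_lt(abs(mean(n1$values - img$values)), 3 * 25 / sqrt(1e6))
  expect_error(add_image_noise(img, -1), "sigma")
})

test_that("healing rule validates its invariants", {
  expect_error(healing_rule(flip_noise = 1.2), "flip_noise")
  expect_error(healing_rule(T_form = 0.1, T_res = 0.2), "T_res")
  expect_error(healing_rule(seed_density = 300), "seed_density")
})

test_that("healing simulation conserves bone and obeys the noiseless rule", {
  geom <- tiny_geom()
  ph <- build_phantom(geom)
  rule <- healing_rule(T_res = 1e-9, flip_noise = 0, rng_seed = 4L)
  sim <- simulate_healing(ph, rule, phantom_loading(), 2L, geom)
  for (t in 1:2) {
    st <- sim$events$steps[[t]]
    bone_t <- sim$series[[t]]$values >= 395
    bone_t1 <- sim$series[[t + 1]]$values >= 395
    # conservation: bone(t+1) = (bone(t) \ resorbed) | formed, exactly
    rebuilt <- bone_t
    rebuilt[st$resorbed] <- FALSE
    rebuilt[st$formed] <- TRUE
    expect_identical(rebuilt, bone_t1)
    expect_length(intersect(st$formed, st$resorbed), 0)
    # every formed voxel was background and exceeded the threshold
    expect_true(all(!bone_t[st$formed]))
    expect_true(all(st$eff_strain[st$formed] > rule$T_form))
  }
})

test_that("zero load produces zero strain and no formation", {
  geom <- tiny_geom()
  ph <- build_phantom(geom)
  sim <- simulate_healing(ph, healing_rule(T_res = 1e-9, flip_noise = 0),
                          phantom_loading(closure = 0), 1L, geom)
  expect_equal(max(sim$events$steps[[1]]$eff_strain), 0)
  expect_length(sim$events$steps[[1]]$formed, 0)
})

test_that("the simulation is bit-identical under a fixed seed", {
  geom <- tiny_geom()
  ph <- build_phantom(geom)
  rule <- healing_rule(flip_noise = 0.1, rng_seed = 21L)
  s1 <- simulate_healing(ph, rule, phantom_loading(), 2L, geom)
  s2 <- simulate_healing(ph, rule, phantom_loading(), 2L, geom)
  expect_identical(lapply(s1$series, `[[`, "values"),
                   lapply(s2$series, `[[`, "values"))
  expect_identical(s1$events$steps, s2$events$steps)
})

test_that("flip noise degrades the downstream ROC monotonically", {
  geom <- tiny_geom()
  ph <- build_phantom(geom)
  for (seed in c(31L, 32L, 33L)) {
    aucs <- vapply(c(0, 0.05, 0.2), function(p) {
      sim <- simulate_healing(ph, healing_rule(flip_noise = p,
                                               rng_seed = seed),
                              phantom_loading(), 2L, geom)
      ov <- overlay(binarize(sim$series[[2]], 395),
                    binarize(sim$series[[3]], 395))
      roc_analysis(sim$events$steps[[2]]$eff_strain, ov)$auc
    }, numeric(1))
    expect_true(all(diff(aucs) <= 0))
  }
})
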