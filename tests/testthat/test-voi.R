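# small phantom with surgical debris for fragment-finding tests
debris_phantom <- function() {
  g <- tiny_geom()
  ph <- build_phantom(g)
  gap <- mechanoct:::phantom_fragment_slices(g)$gap
  mid <- gap[ceiling(length(gap) / 2)]
  # debris: two small blobs at density 700 floating in the gap
  ph$values[9:11, 9:11, mid] <- 700
  ph$values[4:5, 4:5, mid + 2] <- 700
  list(geom = g, image = ph)
}

test_that("fragment labelling keeps the two face-touching components", {
  d <- debris_phantom()
  fr <- find_fragments(d$image)
  sl <- mechanoct:::phantom_fragment_slices(d$geom)
  cortex_count <- sum(mechanoct:::phantom_sections(d$geom)$cortex)
  # per-fragment voxel counts equal the rasterised cortex counts
  expect_identical(sum(fr$proximal), cortex_count * length(sl$proximal))
  expect_identical(sum(fr$distal), cortex_count * length(sl$distal))
  # the 700-density debris is above threshold but discarded
  expect_false(any(fr$proximal[, , sl$gap] | fr$distal[, , sl$gap]))
})

test_that("bridged defects are rejected", {
  d <- debris_phantom()
  # connect the fragments with a dense rod through the gap
  d$image$values[10, 4:6, ] <- 900
  expect_error(find_fragments(d$image), "bridged")
})

test_that("marrow filling produces the solid periosteal volume", {
  g <- phantom_geometry(grid_shape = c(64L, 64L, 24L), voxel_size = 12.5,
                        outer_major_axis = 0.7, outer_minor_axis = 0.5,
                        cortical_thickness = 0.1, gap_length = 0.1)
  ph <- build_phantom(g)
  fr <- find_fragments(ph)
  fc <- fill_marrow(fr)
  h <- 12.5 / 1000
  frag_slices <- 24L - g$gap_vox
  analytic <- pi * 0.35 * 0.25 * frag_slices * h
  expect_equal(sum(fc) * h^3, analytic, tolerance = 0.05)
  # solid fragments: FC equals the fragments themselves
  g2 <- phantom_geometry(grid_shape = c(20L, 20L, 20L), voxel_size = 40,
                         outer_major_axis = 0.6, outer_minor_axis = 0.4,
                         cortical_thickness = 0.2, gap_length = 0.2)
  fr2 <- find_fragments(build_phantom(g2))
  expect_identical(fill_marrow(fr2), fr2$proximal | fr2$distal)
})

test_that("FC is invariant to sub-threshold material", {
  d <- debris_phantom()
  fc1 <- fill_marrow(find_fragments(d$image))
  img2 <- d$image
  set.seed(8)
  low <- array(runif(length(img2$values), 0, 600), dim(img2$values))
  img2$values <- pmax(img2$values, low * (img2$values < 645))
  fc2 <- fill_marrow(find_fragments(img2))
  expect_identical(fc1, fc2)
})

test_that("periosteum interpolation blends the end cross-sections", {
  d <- debris_phantom()
  ph <- build_phantom(d$geom)  # no debris
  fc <- fill_marrow(find_fragments(ph))
  virt <- interpolate_periosteum(fc)
  sl <- mechanoct:::phantom_fragment_slices(d$geom)
  gap <- sl$gap
  zp <- gap[1] - 1L
  # identical aligned end sections: every gap slice reproduces them
  for (z in gap) expect_identical(virt[, , z], fc[, , zp])
  expect_false(any(virt[, , -gap]))
})

test_that("interpolated mid-slice area lies between the end areas", {
  # concentric elliptical ends of different size, built directly
  d <- c(40L, 40L, 21L)
  fc <- array(FALSE, d)
  xy <- expand.grid(x = 1:40, y = 1:40)
  e1 <- with(xy, ((x - 20.5) / 16)^2 + ((y - 20.5) / 10)^2 <= 1)
  e2 <- with(xy, ((x - 20.5) / 8)^2 + ((y - 20.5) / 5)^2 <= 1)
  fc[, , 1] <- e1
  fc[, , 21] <- e2
  virt <- interpolate_periosteum(fc)
  areas <- apply(virt[, , 2:20], 3, sum)
  expect_true(all(areas <= sum(e1) & areas >= sum(e2)))
  # monotone shrink from the large to the small end
  expect_true(all(diff(areas) <= 0))
  # endpoint slices of the gap reproduce the adjacent outlines
  expect_identical(virt[, , 2], matrix(e1, 40, 40))
  expect_identical(virt[, , 20], matrix(e2, 40, 40))
})

test_that("touching fragments yield an empty interpolation with a warning", {
  fc <- array(TRUE, c(6, 6, 6))
  expect_warning(v <- interpolate_periosteum(fc), "no gap")
  expect_false(any(v))
})

test_that("raycast partition is disjoint, exhaustive and symmetric", {
  an <- accept_analysis()
  vois <- an$vois
  total <- vois$DC + vois$DP + vois$FC + vois$FP
  expect_true(all(total == 1L))  # disjoint and covering
  expect_gt(vois$TV_defect, 0)
  expect_gt(vois$TV_fragment, 0)
  # mirror symmetry in x of the phantom implies mirror-symmetric DP
  d <- dim(vois$DP)
  expect_identical(vois$DP, vois$DP[d[1]:1, , ])
  # corner voxels of a gap slice are struck by no surface: defect centre
  gap <- mechanoct:::phantom_fragment_slices(accept_geom())$gap
  mid <- gap[ceiling(length(gap) / 2)]
  expect_true(vois$DC[1, 1, mid])
  expect_true(vois$DC[d[1], d[2], mid])
})

test_that("TV constants are stable under image noise", {
  # VOIs are defined on the unfiltered post-op frame: the 645 threshold is
  # ~10 noise SD above background, whereas filtering a sharp osteotomy edge
  # puts the end slices at 0.707 x cortical density, onto the threshold
  # knife edge
  g <- phantom_geometry(grid_shape = c(64L, 64L, 32L), voxel_size = 12.5,
                        outer_major_axis = 0.7, outer_minor_axis = 0.5,
                        cortical_thickness = 0.12, gap_length = 0.1)
  ph <- build_phantom(g)
  base <- define_vois(ph)
  for (seed in 1:5) {
    v <- define_vois(add_image_noise(ph, 25, rng_seed = seed))
    expect_lt(abs(v$TV_defect - base$TV_defect) / base$TV_defect, 0.02)
    expect_lt(abs(v$TV_fragment - base$TV_fragment) / base$TV_fragment, 0.02)
  }
})
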