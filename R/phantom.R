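#' Phantom geometry
#'
#' Geometry of the synthetic femoral-defect phantom: two hollow
#' elliptical-cylinder cortical fragments separated by an osteotomy gap
#' along the image z axis. Axis lengths are full axes (the murine femoral
#' mid-shaft is an elliptical tube with a 2:1 axis ratio and a 0.2 mm wall;
#' the default tube is scaled down so that it fits the default desk-scale
#' grid while keeping those proportions).
#'
#' @param grid_shape Element grid (3 integers), default `c(96, 96, 160)`.
#' @param voxel_size Voxel edge, micrometres (default 10.5).
#' @param outer_major_axis,outer_minor_axis Full outer axis lengths of the
#'   elliptical cross-section, mm (defaults 0.8 and 0.4).
#' @param cortical_thickness Cortical wall thickness, mm (default 0.1).
#' @param gap_length Osteotomy gap, mm (default 0.85; the alternative
#'   large-defect model uses 1.45).
#' @param cortical_density Cortical mineral density, mg HA/cm^3
#'   (default 900; must exceed the highest segmentation threshold).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_shape = c(96L, 96L, 160L),
                             voxel_size = 10.5,
                             outer_major_axis = 0.8,
                             outer_minor_axis = 0.4,
                             cortical_thickness = 0.1,
                             gap_length = 0.85,
                             cortical_density = 900) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  if (gap_length <= 0) stop("`gap_length` must be positive")
  if (cortical_thickness > min(outer_major_axis, outer_minor_axis) / 2)
    stop("`cortical_thickness` must not exceed half the smallest outer axis")
  if (cortical_density <= 720)
    stop("`cortical_density` must exceed the highest segmentation threshold (720)")
  h <- voxel_size / 1000
  if (outer_major_axis > grid_shape[1] * h)
    stop(sprintf("outer_major_axis (%.3g mm) exceeds grid x extent (%.3g mm)",
                 outer_major_axis, grid_shape[1] * h))
  if (outer_minor_axis > grid_shape[2] * h)
    stop(sprintf("outer_minor_axis (%.3g mm) exceeds grid y extent (%.3g mm)",
                 outer_minor_axis, grid_shape[2] * h))
  gap_vox <- round(gap_length * 1000 / voxel_size)
  if (gap_vox > grid_shape[3] - 2L)
    stop(sprintf("gap_length (%.3g mm = %d slices) leaves no room for fragments in %d slices",
                 gap_length, gap_vox, grid_shape[3]))
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 outer_major_axis = outer_major_axis,
                 outer_minor_axis = outer_minor_axis,
                 cortical_thickness = cortical_thickness,
                 gap_length = gap_length, gap_vox = as.integer(gap_vox),
                 cortical_density = cortical_density),
            class = "phantom_geometry")
}

# 2D logical cross-sections of the tube at voxel centres
phantom_sections <- function(geom) {
  d <- geom$grid_shape
  h <- geom$voxel_size / 1000
  x <- ((seq_len(d[1]) - 0.5) - d[1] / 2) * h
  y <- ((seq_len(d[2]) - 0.5) - d[2] / 2) * h
  a <- geom$outer_major_axis / 2
  b <- geom$outer_minor_axis / 2
  ai <- a - geom$cortical_thickness
  bi <- b - geom$cortical_thickness
  r2 <- outer(x^2 / a^2, y^2 / b^2, "+")
  outer_e <- r2 <= 1
  inner_e <- if (ai > 0 && bi > 0)
    outer(x^2 / ai^2, y^2 / bi^2, "+") < 1 else
    matrix(FALSE, d[1], d[2])
  list(outer = outer_e, cortex = outer_e & !inner_e, marrow = inner_e & outer_e)
}

# axial slice ranges of the two fragments
phantom_fragment_slices <- function(geom) {
  nz <- geom$grid_shape[3]
  n1 <- (nz - geom$gap_vox) %/% 2L
  n2 <- nz - geom$gap_vox - n1
  list(proximal = seq_len(n1), distal = seq.int(nz - n2 + 1L, nz),
       gap = seq.int(n1 + 1L, nz - n2))
}

#' Rasterise the phantom
#'
#' Builds the post-operative density image: two hollow elliptical-cylinder
#' fragments of cortical density touching the two axial image faces,
#' separated by `gap_length` of background (density 0).
#'
#' @param geom A [phantom_geometry()].
#' @return A [density_image()] (frame 0).
#' @export
build_phantom <- function(geom) {
  d <- geom$grid_shape
  sec <- phantom_sections(geom)
  sl <- phantom_fragment_slices(geom)
  v <- array(0, d)
  for (z in c(sl$proximal, sl$distal)) v[, , z][sec$cortex] <- geom$cortical_density
  density_image(v, geom$voxel_size, frame = 0L)
}

#' Mechanostat healing rule for the phantom
#'
#' The generative rule governing the synthetic healing series: soft-tissue
#' voxels within `conduction_radius` (Chebyshev distance, voxels) of
#' existing bone mineralise to `seed_density` when the preceding effective
#' strain exceeds `T_form`; bone surface voxels resorb when it falls below
#' `T_res`; each decision is XOR-ed with an independent Bernoulli
#' (`flip_noise`) disturbance. Existing bone matures by `maturation_rate`
#' per step up to `max_density`.
#'
#' @param T_form Formation threshold on dimensionless effective strain
#'   (default 0.30).
#' @param T_res Resorption threshold (default 2e-4, the classic mechanostat
#'   disuse setpoint of roughly 200 microstrain; must be below `T_form`).
#'   Soft tissue in the defect strains at the 0.1-0.5 level while
#'   mineralised bone strains at the 1e-4 to 1e-3 level, so the resorption
#'   threshold lives on the bone scale: loaded cortex stays,
#'   stress-shielded bone resorbs.
#' @param seed_density Density of newly mineralised voxels, mg HA/cm^3
#'   (default 450; must be at least the lowest ladder threshold).
#' @param maturation_rate Density gain per step, mg HA/cm^3 (default 100).
#' @param max_density Density ceiling, mg HA/cm^3 (default 900).
#' @param flip_noise Probability of a voxel disobeying the rule (default 0).
#' @param conduction_radius Chebyshev radius (voxels) within which new bone
#'   may appear. Default `NULL` resolves at simulation time to
#'   `ceiling(gap_vox / 4)`, which lets the defect bridge within about two
#'   weekly steps -- the healing speed observed for small murine defects at
#'   the lowest density threshold. A fixed integer may be given instead.
#' @param rng_seed Seed for the rule's random flips.
#' @return An object of class `healing_rule`.
#' @export
healing_rule <- function(T_form = 0.30, T_res = 2e-4, seed_density = 450,
                         maturation_rate = 100, max_density = 900,
                         flip_noise = 0, conduction_radius = NULL,
                         rng_seed = 1L) {
  if (flip_noise < 0 || flip_noise > 1) stop("`flip_noise` must be in [0, 1]")
  if (T_res >= T_form) stop("`T_res` must be below `T_form`")
  if (seed_density < 395)
    stop("`seed_density` must be at least the lowest ladder threshold (395)")
  structure(list(T_form = T_form, T_res = T_res, seed_density = seed_density,
                 maturation_rate = maturation_rate, max_density = max_density,
                 flip_noise = flip_noise,
                 conduction_radius = if (is.null(conduction_radius)) NULL else
                   as.integer(conduction_radius),
                 rng_seed = as.integer(rng_seed)),
            class = "healing_rule")
}

#' Phantom loading configuration
#'
#' Either a physiological spring mode, in which the axial load `F_axial` is
#' shared between the fixator (`k_fixator`) and the callus (stiffness probed
#' from the current image) so that the interface closing displacement is
#' `u = F_axial / (k_fixator + k_callus)`, or a fixed-displacement mode in
#' which `closure` (mm) is applied directly at every step.
#'
#' @param F_axial Axial compressive load, N (default 10, the reported
#'   physiological estimate for the mouse femur).
#' @param k_fixator Axial fixator stiffness, N/mm (default 25; chosen, with
#'   the 10 N load, so that the post-operative nominal gap strain of the
#'   default phantom sits near 0.45, the regime of the reported optimal
#'   effective strain in a healing defect at the onset of hard-callus
#'   formation).
#' @param closure Optional fixed closing displacement, mm; when given, the
#'   spring model is bypassed.
#' @param tol Relative residual tolerance for the per-step FE solves.
#' @return An object of class `phantom_loading`.
#' @export
phantom_loading <- function(F_axial = 10, k_fixator = 25, closure = NULL,
                            tol = 1e-6) {
  if (is.null(closure)) {
    if (F_axial < 0) stop("`F_axial` must be non-negative (compression)")
    if (k_fixator <= 0) stop("`k_fixator` must be positive")
  }
  structure(list(F_axial = F_axial, k_fixator = k_fixator,
                 closure = closure, tol = tol),
            class = "phantom_loading")
}

# bone voxels with at least one 6-neighbour in `other` (outside the grid
# counts as neither)
face_adjacent <- function(mask, other) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sh <- function(m, axis, dir) {
    r <- array(FALSE, d)
    if (axis == 1) {
      if (dir > 0) r[1:(d[1] - 1), , ] <- m[2:d[1], , ]
      else r[2:d[1], , ] <- m[1:(d[1] - 1), , ]
    } else if (axis == 2) {
      if (dir > 0) r[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
      else r[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
    } else {
      if (dir > 0) r[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
      else r[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
    }
    r
  }
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out | sh(other, axis, dir)
  mask & out
}

dilate_mask <- function(mask, radius) {
  d <- dim(mask)
  array(.dilate_chebyshev_cpp(as.logical(mask), as.integer(d),
                              as.integer(radius)), d)
}

#' Simulate a time-lapsed healing series
#'
#' Runs the mechanostat [healing_rule()] forward from the post-operative
#' phantom: at each step a voxel micro-FE solve on the current density image
#' (threshold-band material model) provides the effective-strain stimulus,
#' new bone forms in the conduction zone above the formation threshold,
#' surface bone below the resorption threshold resorbs, and existing bone
#' matures. The applied boundary displacement follows the two-spring
#' fixator/callus model, with the callus stiffness re-estimated every step
#' from the face reaction inside the periosteal footprint (stress
#' shielding). Every event and every preceding strain field is recorded.
#'
#' @param phantom Post-operative [density_image()] from [build_phantom()].
#' @param rule A [healing_rule()].
#' @param loading A [phantom_loading()].
#' @param n_steps Number of weekly steps (>= 1).
#' @param geom The [phantom_geometry()] used to build the phantom (supplies
#'   the stiffness-probe region).
#' @param ladder [threshold_ladder()] for the material model.
#' @return List with `series` (list of `density_image`, frames 0..n_steps)
#'   and `events` (class `event_log`: per step the indices truly formed,
#'   resorbed and matured, the preceding effective-strain field, the applied
#'   closure and the callus stiffness).
#' @export
simulate_healing <- function(phantom, rule, loading, n_steps, geom,
                             ladder = threshold_ladder()) {
  stopifnot(n_steps >= 1)
  set.seed(rule$rng_seed)
  if (is.null(rule$conduction_radius))
    rule$conduction_radius <- as.integer(ceiling(geom$gap_vox / 4))
  d <- dim(phantom$values)
  soft_thr <- min(ladder)
  sec <- phantom_sections(geom)
  region <- array(rep(sec$outer, d[3]), d)  # periosteal column
  series <- vector("list", n_steps + 1L)
  series[[1L]] <- phantom
  steps <- vector("list", n_steps)
  D <- phantom$values
  k_callus <- NA_real_
  for (t in seq_len(n_steps)) {
    mat <- material_from_image(density_image(D, phantom$voxel_size),
                               ladder = ladder)
    if (is.null(loading$closure)) {
      if (is.na(k_callus)) {
        probe <- axial_stiffness(mat, region = region, tol = loading$tol)
        k_callus <- probe$k
      }
      u <- loading$F_axial / (loading$k_fixator + k_callus)
    } else {
      u <- loading$closure
    }
    bc <- bc_axial(d, phantom$voxel_size, u)
    field <- fe_solve(mat, bc, tol = loading$tol)
    if (is.null(loading$closure) && u > 0) {
      k_callus <- footprint_stiffness(field, sec$outer, u)
    }
    eps <- field$eff_strain
    bone <- D >= soft_thr
    cand <- !bone & dilate_mask(bone, rule$conduction_radius)
    ci <- which(cand)
    flips_f <- runif(length(ci)) < rule$flip_noise
    formed <- ci[xor(eps[ci] > rule$T_form, flips_f)]
    surf <- face_adjacent(bone, !bone)
    si <- which(surf)
    flips_r <- runif(length(si)) < rule$flip_noise
    resorbed <- si[xor(eps[si] < rule$T_res, flips_r)]
    keep <- bone
    keep[resorbed] <- FALSE
    matured <- which(keep & D < rule$max_density)
    D[keep] <- pmin(D[keep] + rule$maturation_rate, rule$max_density)
    D[resorbed] <- 0
    D[formed] <- rule$seed_density
    series[[t + 1L]] <- density_image(D, phantom$voxel_size, frame = t)
    steps[[t]] <- list(formed = formed, resorbed = resorbed,
                       matured = matured, eff_strain = eps,
                       closure = u, k_callus = k_callus)
  }
  events <- structure(list(steps = steps, rule = rule, loading = loading,
                           soft_threshold = soft_thr),
                      class = "event_log")
  list(series = series, events = events)
}

# callus stiffness from the z reaction summed over face nodes inside the
# periosteal footprint
footprint_stiffness <- function(field, footprint, closure) {
  dims <- field$dims
  nn <- dims + 1L
  fn <- matrix(FALSE, nn[1], nn[2])
  ij <- which(footprint, arr.ind = TRUE)
  for (dd in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
    fn[cbind(ij[, 1] + dd[1], ij[, 2] + dd[2])] <- TRUE
  idx <- which(fn, arr.ind = TRUE) - 1L
  nodes <- node_index(idx[, 1], idx[, 2], dims[3], nn)
  fz <- sum(field$force[3 * (nodes - 1) + 3])
  abs(fz) / closure
}

#' Add CT-like image noise
#'
#' Additive zero-mean Gaussian noise, clipped at zero density.
#'
#' @param image A [density_image()].
#' @param sigma Noise standard deviation, mg HA/cm^3 (>= 0).
#' @param rng_seed Seed for reproducibility.
#' @return Noisy [density_image()].
#' @export
add_image_noise <- function(image, sigma, rng_seed = 1L) {
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(image)
  set.seed(rng_seed)
  v <- image$values + rnorm(length(image$values), 0, sigma)
  v[v < 0] <- 0
  density_image(array(v, dim(image$values)), image$voxel_size, image$frame)
}
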