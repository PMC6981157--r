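# Independent oracles and shared fixtures. Everything here is written
# against the maths directly (dense assembly, pair counting, double loops)
# and deliberately avoids the package's computational kernels.

# ---- dense finite-element oracle -------------------------------------------

# Element stiffness of a trilinear hexahedron of edge h, modulus E, ratio nu,
# derived here from scratch by 2x2x2 Gauss quadrature on the physical element.
oracle_hex_stiffness <- function(E, nu, h) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  gp <- h / 2 + c(-1, 1) * h / (2 * sqrt(3))
  K <- matrix(0, 24, 24)
  for (gx in gp) for (gy in gp) for (gz in gp) {
    B <- matrix(0, 6, 24)
    for (l in 0:7) {
      dx <- bitwAnd(l, 1L) > 0
      dy <- bitwAnd(l, 2L) > 0
      dz <- bitwAnd(l, 4L) > 0
      fx <- if (dx) gx / h else 1 - gx / h
      fy <- if (dy) gy / h else 1 - gy / h
      fz <- if (dz) gz / h else 1 - gz / h
      gdx <- (if (dx) 1 else -1) / h * fy * fz
      gdy <- fx * (if (dy) 1 else -1) / h * fz
      gdz <- fx * fy * (if (dz) 1 else -1) / h
      c0 <- 3 * l
      B[1, c0 + 1] <- gdx
      B[2, c0 + 2] <- gdy
      B[3, c0 + 3] <- gdz
      B[4, c0 + 1] <- gdy; B[4, c0 + 2] <- gdx
      B[5, c0 + 2] <- gdz; B[5, c0 + 3] <- gdy
      B[6, c0 + 1] <- gdz; B[6, c0 + 3] <- gdx
    }
    K <- K + (h / 2)^3 * t(B) %*% D %*% B
  }
  K
}

# Explicitly assembled global system solved by dense direct factorisation.
oracle_dense_solve <- function(E_arr, voxel_um, bc, nu = 0.3) {
  dims <- dim(E_arr)
  h <- voxel_um / 1000
  nn <- dims + 1L
  ndof <- 3 * prod(nn)
  Kel_unit <- oracle_hex_stiffness(1, nu, h)
  K <- matrix(0, ndof, ndof)
  for (iz in 0:(dims[3] - 1)) for (iy in 0:(dims[2] - 1))
    for (ix in 0:(dims[1] - 1)) {
      nodes <- integer(8)
      l <- 1
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        nodes[l] <- 1 + (ix + dx) + nn[1] * ((iy + dy) + nn[2] * (iz + dz))
        l <- l + 1
      }
      dofs <- as.vector(rbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2,
                              3 * (nodes - 1) + 3))
      K[dofs, dofs] <- K[dofs, dofs] + E_arr[ix + 1, iy + 1, iz + 1] * Kel_unit
    }
  u <- numeric(ndof)
  u[bc$dofs] <- bc$values
  free <- setdiff(seq_len(ndof), bc$dofs)
  rhs <- -K[free, bc$dofs, drop = FALSE] %*% bc$values
  u[free] <- solve(K[free, free], rhs)
  u
}

# ---- statistics oracles ----------------------------------------------------

# Mann-Whitney two-sample statistic by direct pair counting:
# P(S_pos > S_neg) + 1/2 P(S_pos == S_neg)
oracle_mw_auc <- function(s, truth) {
  sp <- s[truth]
  sn <- s[!truth]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Exhaustive double-loop CCR sweep (independent of ccr_heatmap internals);
# returns max and lexicographically smallest argmax over the same grid.
# Diagonal terms are accumulated in the R, F, Q order so the floating-point
# sum is comparable bit-for-bit.
oracle_ccr_sweep <- function(signal, state, thr) {
  best <- -Inf
  arg <- c(NA, NA)
  nt <- sapply(c("F", "Q", "R"), function(l) sum(state == l))
  for (i in seq_along(thr)) for (j in seq_along(thr)) {
    if (thr[i] >= thr[j]) next
    pred <- ifelse(signal > thr[j], "F", ifelse(signal < thr[i], "R", "Q"))
    cc <- 0
    for (l in c("R", "F", "Q")) if (nt[[l]] > 0)
      cc <- cc + sum(pred == l & state == l) / nt[[l]]
    cc <- cc / 3
    if (cc > best) {
      best <- cc
      arg <- c(thr[i], thr[j])
    }
  }
  list(max = best, T_R = arg[1], T_F = arg[2])
}

# ---- shared phantom worlds -------------------------------------------------

# Desk-scale world used by heavier tests: same physical defect as the
# defaults (0.85 mm gap, 0.8 x 0.4 mm tube) at 30 um voxels.
accept_geom <- function() {
  phantom_geometry(grid_shape = c(32L, 32L, 56L), voxel_size = 30,
                   outer_major_axis = 0.8, outer_minor_axis = 0.4,
                   cortical_thickness = 0.1, gap_length = 0.85)
}

# Minimal world for fast property tests.
tiny_geom <- function() {
  phantom_geometry(grid_shape = c(20L, 20L, 32L), voxel_size = 40,
                   outer_major_axis = 0.72, outer_minor_axis = 0.44,
                   cortical_thickness = 0.12, gap_length = 0.85)
}

# Memoised expensive fixtures (helpers persist for the whole test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# The canonical acceptance run: 5 steps, T* = 0.30, flip 0.02, fixed seed.
accept_sim <- function() {
  cached("accept_sim", function() {
    geom <- accept_geom()
    sim <- simulate_healing(build_phantom(geom),
                            healing_rule(flip_noise = 0.02, rng_seed = 101L),
                            phantom_loading(), n_steps = 5L, geom)
    sim$geom <- geom
    sim
  })
}

# Smoothed frames + VOI partition of the acceptance run.
accept_analysis <- function() {
  cached("accept_analysis", function() {
    sim <- accept_sim()
    smooth <- lapply(sim$series, gaussian_smooth)
    vois <- define_vois(sim$series[[1]])
    list(smooth = smooth, vois = vois)
  })
}
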