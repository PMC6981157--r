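#' Density to Young's modulus conversion
#'
#' Maps mineral density to an isotropic Young's modulus. Densities below the
#' lowest segmentation threshold are soft tissue (3 MPa). Bone moduli follow
#' a linear ramp anchored at 4 GPa for 395 mg HA/cm^3 and 14 GPa for
#' 720 mg HA/cm^3. In the default `"band"` mode each voxel takes the modulus
#' of the highest ladder threshold it exceeds (the multi-density threshold
#' model); `"continuous"` mode applies the linear law to the raw density
#' (sensitivity analyses only). Densities above the top threshold clamp to
#' the 14 GPa anchor.
#'
#' @param density Numeric vector or array of densities, mg HA/cm^3.
#' @param ladder A [threshold_ladder()].
#' @param mode `"band"` (default) or `"continuous"`.
#' @param E_soft Soft-tissue modulus, MPa (default 3).
#' @param E_low,E_high Moduli at the lowest/highest ladder thresholds, MPa.
#' @return Young's moduli in MPa, same shape as `density`.
#' @export
density_to_modulus <- function(density, ladder = threshold_ladder(),
                               mode = c("band", "continuous"),
                               E_soft = 3, E_low = 4000, E_high = 14000) {
  mode <- match.arg(mode)
  if (any(density < 0)) stop("densities must be non-negative")
  tau <- as.numeric(ladder)
  t_lo <- tau[1L]
  t_hi <- tau[length(tau)]
  if (mode == "band") {
    # highest threshold <= density; 0 bands -> soft tissue
    band <- findInterval(density, tau)
    eff <- ifelse(band > 0L, tau[pmax(band, 1L)], NA_real_)
  } else {
    eff <- ifelse(density >= t_lo, pmin(density, t_hi), NA_real_)
  }
  E <- E_low + (E_high - E_low) * (pmin(eff, t_hi) - t_lo) / (t_hi - t_lo)
  E[is.na(eff)] <- E_soft
  if (is.array(density)) array(E, dim(density)) else E
}

#' Material map for a voxel FE model
#'
#' One hexahedral element per voxel; per-element Young's modulus, a uniform
#' Poisson's ratio and the element edge length.
#'
#' @param E 3D array of Young's moduli, MPa (all > 0).
#' @param voxel_size Voxel edge, micrometres.
#' @param nu Poisson's ratio (default 0.3, the value used throughout).
#' @return An object of class `material_map`.
#' @export
material_map <- function(E, voxel_size, nu = 0.3) {
  if (!is.array(E) || length(dim(E)) != 3L) stop("`E` must be a 3D array")
  if (any(E <= 0)) stop("all moduli must be positive")
  if (nu <= 0 || nu >= 0.5) stop("`nu` must be in (0, 0.5)")
  structure(list(E = E, voxel_size = as.numeric(voxel_size), nu = nu),
            class = "material_map")
}

#' Material map from a density image
#'
#' @param image A [density_image()].
#' @inheritParams density_to_modulus
#' @param nu Poisson's ratio.
#' @return A [material_map()].
#' @export
material_from_image <- function(image, ladder = threshold_ladder(),
                                mode = c("band", "continuous"),
                                E_soft = 3, E_low = 4000, E_high = 14000,
                                nu = 0.3) {
  E <- density_to_modulus(image$values, ladder, match.arg(mode),
                          E_soft, E_low, E_high)
  material_map(E, image$voxel_size, nu)
}

# ---- reference element ----

# 24x24 stiffness of the unit-cube trilinear hexahedron, E = 1, given nu.
# 2x2x2 Gauss quadrature (exact for this element). Element stiffness at
# edge h and modulus E is E * h * K0.
hex8_reference_stiffness <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- 0.5 + c(-1, 1) / (2 * sqrt(3))
  K <- matrix(0, 24, 24)
  shp <- function(t, d) if (d) t else 1 - t   # node factor
  dshp <- function(d) if (d) 1 else -1
  for (gx in gp) for (gy in gp) for (gz in gp) {
    B <- matrix(0, 6, 24)
    for (l in 0:7) {
      dx <- bitwAnd(l, 1L) > 0; dy <- bitwAnd(l, 2L) > 0; dz <- bitwAnd(l, 4L) > 0
      dNdx <- dshp(dx) * shp(gy, dy) * shp(gz, dz)
      dNdy <- shp(gx, dx) * dshp(dy) * shp(gz, dz)
      dNdz <- shp(gx, dx) * shp(gy, dy) * dshp(dz)
      c0 <- 3 * l
      B[1, c0 + 1] <- dNdx
      B[2, c0 + 2] <- dNdy
      B[3, c0 + 3] <- dNdz
      B[4, c0 + 1] <- dNdy; B[4, c0 + 2] <- dNdx
      B[5, c0 + 2] <- dNdz; B[5, c0 + 3] <- dNdy
      B[6, c0 + 1] <- dNdz; B[6, c0 + 3] <- dNdx
    }
    K <- K + (1 / 8) * t(B) %*% D %*% B
  }
  K
}

.k0_cache <- new.env(parent = emptyenv())

reference_stiffness <- function(nu) {
  key <- format(nu, digits = 15)
  if (is.null(.k0_cache[[key]]))
    .k0_cache[[key]] <- hex8_reference_stiffness(nu)
  .k0_cache[[key]]
}

# ---- boundary conditions ----

new_bc_spec <- function(dofs, values, dims, description) {
  o <- order(dofs)
  dofs <- dofs[o]; values <- values[o]
  keep <- !duplicated(dofs)
  structure(list(dofs = as.integer(dofs[keep]), values = values[keep],
                 dims = as.integer(dims), description = description),
            class = "bc_spec")
}

node_grid <- function(dims) {
  nn <- dims + 1L
  list(nn = nn, n_nodes = prod(nn))
}

# 1-based node index from 0-based lattice coordinates
node_index <- function(ix, iy, iz, nn) 1L + ix + nn[1] * (iy + nn[2] * iz)

#' Affine displacement boundary conditions
#'
#' Prescribes `u = eps %*% x` on every boundary node of the grid, where
#' `eps` is a constant small-strain tensor. Used for patch tests and for
#' confined-compression probes.
#'
#' @param dims Element grid dimensions (3 integers).
#' @param voxel_size Voxel edge, micrometres.
#' @param strain 3x3 symmetric strain tensor (engineering definition on the
#'   diagonal; tensor shears off-diagonal).
#' @return A `bc_spec`.
#' @export
bc_affine <- function(dims, voxel_size, strain) {
  stopifnot(is.matrix(strain), all(dim(strain) == c(3, 3)))
  h <- voxel_size / 1000
  nn <- dims + 1L
  ix <- seq_len(nn[1]) - 1L; iy <- seq_len(nn[2]) - 1L; iz <- seq_len(nn[3]) - 1L
  g <- expand.grid(ix = ix, iy = iy, iz = iz)
  on_bnd <- g$ix == 0L | g$ix == dims[1] | g$iy == 0L | g$iy == dims[2] |
    g$iz == 0L | g$iz == dims[3]
  gb <- g[on_bnd, ]
  X <- cbind(gb$ix, gb$iy, gb$iz) * h
  U <- X %*% t(strain)
  nodes <- node_index(gb$ix, gb$iy, gb$iz, nn)
  dofs <- as.integer(rbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2,
                           3 * (nodes - 1) + 3))
  vals <- as.numeric(t(U))
  new_bc_spec(dofs, vals, dims, "affine boundary displacement")
}

#' Axial-face displacement boundary conditions
#'
#' Prescribes the z-displacement on the two axial image faces (z = 0 moves by
#' `+closure/2`, z = L by `-closure/2`, i.e. a positive `closure` compresses).
#' Transverse faces are traction-free. In-plane rigid-body modes are removed
#' by pinning: node (0,0,0) is fixed in x and y, node (nx,0,0) in y.
#'
#' @param dims Element grid dimensions.
#' @param voxel_size Voxel edge, micrometres.
#' @param closure Total closing displacement between the axial faces, mm.
#' @param clamp_transverse If TRUE, also fix x and y on the axial faces
#'   (confined compression).
#' @param face_nodes Optional logical 2D array (nx+1 x ny+1): restrict the
#'   prescription to these in-plane node positions (used by the stiffness
#'   probe when only a sub-region is loaded).
#' @return A `bc_spec`.
#' @export
bc_axial <- function(dims, voxel_size, closure, clamp_transverse = FALSE,
                     face_nodes = NULL) {
  nn <- dims + 1L
  if (is.null(face_nodes)) {
    face_nodes <- matrix(TRUE, nn[1], nn[2])
  }
  stopifnot(all(dim(face_nodes) == nn[1:2]))
  idx <- which(face_nodes, arr.ind = TRUE) - 1L
  bot <- node_index(idx[, 1], idx[, 2], 0L, nn)
  top <- node_index(idx[, 1], idx[, 2], dims[3], nn)
  dofs <- c(3 * (bot - 1) + 3, 3 * (top - 1) + 3)
  vals <- c(rep(closure / 2, length(bot)), rep(-closure / 2, length(top)))
  if (clamp_transverse) {
    dofs <- c(dofs, 3 * (bot - 1) + 1, 3 * (bot - 1) + 2,
              3 * (top - 1) + 1, 3 * (top - 1) + 2)
    vals <- c(vals, rep(0, 2 * length(bot) + 2 * length(top)))
  } else {
    pin1 <- node_index(0L, 0L, 0L, nn)
    pin2 <- node_index(dims[1], 0L, 0L, nn)
    dofs <- c(dofs, 3 * (pin1 - 1) + 1, 3 * (pin1 - 1) + 2, 3 * (pin2 - 1) + 2)
    vals <- c(vals, 0, 0, 0)
  }
  new_bc_spec(dofs, vals, dims,
              sprintf("axial closure %.6g mm", closure))
}

#' Axial face boundary condition with a bending gradient
#'
#' Optional extension of [bc_axial()]: adds a linear axial-displacement
#' gradient across the face (rotation about the y axis), used for bending
#' unit load cases.
#'
#' @inheritParams bc_axial
#' @param theta Rotation angle (radians); axial displacement varies as
#'   `+/- theta * (x - xc)` on the two faces.
#' @return A `bc_spec`.
#' @export
bc_axial_bending <- function(dims, voxel_size, theta) {
  h <- voxel_size / 1000
  nn <- dims + 1L
  idx <- which(matrix(TRUE, nn[1], nn[2]), arr.ind = TRUE) - 1L
  xc <- dims[1] * h / 2
  x <- idx[, 1] * h - xc
  bot <- node_index(idx[, 1], idx[, 2], 0L, nn)
  top <- node_index(idx[, 1], idx[, 2], dims[3], nn)
  dofs <- c(3 * (bot - 1) + 3, 3 * (top - 1) + 3)
  vals <- c(theta / 2 * x, -theta / 2 * x)
  pin1 <- node_index(0L, 0L, 0L, nn)
  pin2 <- node_index(dims[1], 0L, 0L, nn)
  dofs <- c(dofs, 3 * (pin1 - 1) + 1, 3 * (pin1 - 1) + 2, 3 * (pin2 - 1) + 2)
  vals <- c(vals, 0, 0, 0)
  new_bc_spec(dofs, vals, dims, sprintf("axial bending theta %.6g rad", theta))
}

# ---- solver ----

#' Solve a voxel finite-element model
#'
#' Linear elasticity on the structured voxel grid: 8-node trilinear
#' hexahedra, one element per voxel, all elements geometrically identical
#' (a single reference stiffness matrix scaled by the element modulus).
#' The system is solved matrix-free with Jacobi-preconditioned conjugate
#' gradients. Strain-energy density and effective strain
#' `eps_eff = sqrt(2 U / E)` are evaluated at element centroids (the mean of
#' the 2x2x2 Gauss points).
#'
#' @param material A [material_map()].
#' @param bc A `bc_spec` (see [bc_axial()], [bc_affine()]).
#' @param tol Relative residual tolerance (default 1e-8).
#' @param maxit Iteration cap; defaults to `20 * max(dims)` plus a floor.
#' @return An object of class `strain_field`: element-wise `eff_strain` and
#'   `sed` (3D arrays), the 6-column centroid strain matrix `strain`
#'   (exx, eyy, ezz, gxy, gyz, gxz), nodal displacements `u` (mm), the nodal
#'   force vector `force` (N), solver diagnostics, and grid metadata.
#' @export
fe_solve <- function(material, bc, tol = 1e-8, maxit = NULL) {
  dims <- dim(material$E)
  if (!identical(as.integer(dims), bc$dims))
    stop("material and boundary conditions disagree on grid shape")
  h <- material$voxel_size / 1000
  K0 <- reference_stiffness(material$nu)
  if (is.null(maxit)) maxit <- max(2000L, 40L * max(dims))
  res <- .fe_pcg_cpp(as.numeric(material$E), as.integer(dims), K0, h,
                     bc$dofs - 1L, bc$values, tol, as.integer(maxit))
  if (!res$converged && res$relres > tol)
    stop(sprintf(paste0("FE solve did not converge: relative residual %.3e ",
                        "after %d iterations (tol %.1e)"),
                 res$relres, res$iterations, tol),
         call. = FALSE)
  strain <- .fe_centroid_strain_cpp(res$u, as.integer(dims), h)
  sed_v <- sed_from_strain(strain, as.numeric(material$E), material$nu)
  eff_v <- sqrt(2 * sed_v / as.numeric(material$E))
  force <- .fe_matvec_cpp(res$u, as.numeric(material$E), as.integer(dims),
                          K0, h)
  structure(list(eff_strain = array(eff_v, dims),
                 sed = array(sed_v, dims),
                 strain = strain,
                 u = res$u,
                 force = force,
                 residual = res$relres,
                 iterations = res$iterations,
                 history = res$history,
                 dims = as.integer(dims),
                 voxel_size = material$voxel_size,
                 nu = material$nu),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d x %d x %d elements, relres %.2e (%d it)\n",
              x$dims[1], x$dims[2], x$dims[3], x$residual, x$iterations))
  cat(sprintf("  eff_strain range [%.4g, %.4g]\n",
              min(x$eff_strain), max(x$eff_strain)))
  invisible(x)
}

# SED per element from 6-component centroid strains (engineering shears):
# U = 1/2 lam tr(e)^2 + mu (exx^2+eyy^2+ezz^2) + mu/2 (gxy^2+gyz^2+gxz^2)
sed_from_strain <- function(strain, E, nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu)) * E
  mu <- E / (2 * (1 + nu))
  tr <- strain[, 1] + strain[, 2] + strain[, 3]
  nrm2 <- strain[, 1]^2 + strain[, 2]^2 + strain[, 3]^2
  sh2 <- strain[, 4]^2 + strain[, 5]^2 + strain[, 6]^2
  0.5 * lam * tr^2 + mu * nrm2 + 0.5 * mu * sh2
}

#' Reaction force on an axial face
#'
#' Sums the nodal force components over one axial face of the grid.
#'
#' @param field A `strain_field` from [fe_solve()].
#' @param face `"z0"` (bottom) or `"z1"` (top).
#' @return Numeric length-3 force vector (N), image axes order.
#' @export
face_reaction <- function(field, face = c("z1", "z0")) {
  face <- match.arg(face)
  dims <- field$dims
  nn <- dims + 1L
  iz <- if (face == "z0") 0L else dims[3]
  idx <- which(matrix(TRUE, nn[1], nn[2]), arr.ind = TRUE) - 1L
  nodes <- node_index(idx[, 1], idx[, 2], iz, nn)
  f <- field$force
  c(sum(f[3 * (nodes - 1) + 1]), sum(f[3 * (nodes - 1) + 2]),
    sum(f[3 * (nodes - 1) + 3]))
}

#' Axial stiffness probe
#'
#' Prescribes a 1% axial compressive displacement across a region (by
#' default the whole grid; for healing images, the cortical bone plus marrow
#' column) with free transverse faces, and reports
#' `k = reaction force / applied displacement` in N/mm.
#'
#' Elements outside `region` are softened to `1e-3 * min(E in region)` so
#' that they carry a negligible share of the load while keeping the
#' stiffness matrix definite; the displacement is prescribed only on face
#' nodes touching region elements.
#'
#' @param material A [material_map()].
#' @param region Optional logical 3D array selecting the probed elements;
#'   must span the full axial extent.
#' @param strain Applied compressive strain (default 0.01, i.e. 1%).
#' @param tol,maxit Solver controls, see [fe_solve()].
#' @return List with `k` (N/mm), `closure` (mm) and the `strain_field`.
#' @export
axial_stiffness <- function(material, region = NULL, strain = 0.01,
                            tol = 1e-8, maxit = NULL) {
  dims <- dim(material$E)
  h <- material$voxel_size / 1000
  L <- dims[3] * h
  closure <- strain * L
  E <- material$E
  face_nodes <- NULL
  if (!is.null(region)) {
    stopifnot(identical(dim(region), dims))
    if (!any(region[, , 1]) || !any(region[, , dims[3]]))
      stop("`region` must span the axial extent of the grid")
    floorE <- 1e-3 * min(E[region])
    E <- ifelse(region, E, pmin(E, floorE))
    # face nodes touched by region elements on the bottom/top slices
    face_elems <- region[, , 1] | region[, , dims[3]]
    fn <- matrix(FALSE, dims[1] + 1L, dims[2] + 1L)
    ij <- which(face_elems, arr.ind = TRUE)
    for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
      fn[cbind(ij[, 1] + d[1], ij[, 2] + d[2])] <- TRUE
    face_nodes <- fn
    material <- material_map(E, material$voxel_size, material$nu)
  }
  bc <- bc_axial(dims, material$voxel_size, closure, face_nodes = face_nodes)
  field <- fe_solve(material, bc, tol = tol, maxit = maxit)
  fz_top <- face_reaction(field, "z1")[3]
  # top face moves by -closure/2; compression gives negative fz there
  k <- abs(fz_top) / (closure / 2) / 2
  list(k = k, closure = closure, field = field)
}
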