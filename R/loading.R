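#' Unit load cases on an intact shaft model
#'
#' Solves the voxel FE model for unit-magnitude load cases: axial
#' compression (normalised to 1 N) and, optionally, a bending moment about
#' the minor ellipticity axis of the cross-section (normalised to 1 Nmm).
#' Displacement-controlled solves are rescaled by the resulting face
#' reaction (force or moment), which is exact under linearity.
#'
#' @param material A [material_map()] of the intact shaft.
#' @param kinds Character vector from `c("axial", "bending")`.
#' @param tol Solver tolerance.
#' @return List of `load_case` objects: `kind`, `magnitude` (1 N or 1 Nmm),
#'   6-column element strain matrix `strain` per unit load, `sed` per unit
#'   load, and solve metadata.
#' @export
unit_load_cases <- function(material, kinds = c("axial", "bending"),
                            tol = 1e-8) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  dims <- dim(material$E)
  h <- material$voxel_size / 1000
  out <- list()
  for (kind in kinds) {
    if (kind == "axial") {
      bc <- bc_axial(dims, material$voxel_size, closure = 0.001 * dims[3] * h)
      field <- fe_solve(material, bc, tol = tol)
      Fz <- abs(face_reaction(field, "z1")[3])
      if (Fz <= 0) stop("degenerate axial case: zero reaction")
      scale <- 1 / Fz
    } else {
      bc <- bc_axial_bending(dims, material$voxel_size, theta = 1e-3)
      field <- fe_solve(material, bc, tol = tol)
      M <- abs(face_moment_y(field, h))
      if (M <= 0) stop("degenerate bending case: zero moment")
      scale <- 1 / M
    }
    strain <- field$strain * scale
    out[[kind]] <- structure(
      list(kind = kind, magnitude = 1,
           strain = strain,
           E = as.numeric(material$E), nu = material$nu,
           dims = dims, voxel_size = material$voxel_size),
      class = "load_case")
  }
  out
}

# moment about the y axis (through the section centroid) of the top-face
# axial reactions, Nmm
face_moment_y <- function(field, h) {
  dims <- field$dims
  nn <- dims + 1L
  idx <- which(matrix(TRUE, nn[1], nn[2]), arr.ind = TRUE) - 1L
  nodes <- node_index(idx[, 1], idx[, 2], dims[3], nn)
  x <- idx[, 1] * h - dims[1] * h / 2
  sum(field$force[3 * (nodes - 1) + 3] * x)
}

#' Physiological load estimation
#'
#' Finds non-negative scale factors for the unit load cases such that the
#' superposed strain field produces a strain-energy density as homogeneous
#' as possible at the target tissue loading level over the bone elements:
#' minimises `sum_e (U_e(s) - U_target)^2`. The SED of the combination is
#' quadratic in the scale factors and is computed from the superposed
#' strain tensor, not by superposing SEDs. Optimised by bounded
#' quasi-Newton from multiple starts; ties resolved by the smallest-norm
#' solution.
#'
#' @param cases List of `load_case` from [unit_load_cases()].
#' @param bone_mask Logical 3D array of bone elements to match.
#' @param U_target Target strain-energy density, MPa (default 0.02).
#' @return An object of class `load_estimate`: `F_axial` (N), `M_bend`
#'   (Nmm; 0 if no bending case), `scales`, `residual`, `U_target`.
#' @export
estimate_load <- function(cases, bone_mask, U_target = 0.02) {
  if (length(cases) < 1L) stop("need at least one load case")
  sel <- which(as.logical(bone_mask))
  if (length(sel) == 0L) stop("empty bone mask")
  E <- cases[[1]]$E[sel]
  nu <- cases[[1]]$nu
  eps_list <- lapply(cases, function(cs) cs$strain[sel, , drop = FALSE])
  if (all(vapply(eps_list, function(m) all(m == 0), logical(1))))
    stop("degenerate load cases: zero strain fields on the bone mask")
  ncase <- length(eps_list)
  sed_comb <- function(s) {
    acc <- eps_list[[1]] * s[1]
    if (ncase > 1)
      for (k in 2:ncase) acc <- acc + eps_list[[k]] * s[k]
    sed_from_strain(acc, E, nu)
  }
  obj <- function(s) sum((sed_comb(s) - U_target)^2)
  # closed-form single-case magnitudes as starts
  starts <- list()
  for (k in seq_len(ncase)) {
    Uk <- mean(sed_from_strain(eps_list[[k]], E, nu))
    s0 <- rep(0, ncase)
    s0[k] <- if (Uk > 0) sqrt(U_target / Uk) else 1
    starts[[length(starts) + 1L]] <- s0
  }
  starts[[length(starts) + 1L]] <- Reduce(`+`, starts) / ncase
  best <- NULL
  for (s0 in starts) {
    fit <- optim(s0, obj, method = "L-BFGS-B", lower = rep(0, ncase),
                 control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value - 1e-12 * (1 + best$value) ||
        (abs(fit$value - best$value) <= 1e-12 * (1 + best$value) &&
         sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  s <- best$par
  names(s) <- vapply(cases, function(cs) cs$kind, character(1))
  structure(list(F_axial = unname(if ("axial" %in% names(s)) s[["axial"]] else 0),
                 M_bend = unname(if ("bending" %in% names(s)) s[["bending"]] else 0),
                 scales = s, residual = best$value, U_target = U_target),
            class = "load_estimate")
}

#' @export
print.load_estimate <- function(x, ...) {
  cat(sprintf("<load_estimate> F_axial %.3f N, M_bend %.3f Nmm (residual %.3e, U_target %.3g MPa)\n",
              x$F_axial, x$M_bend, x$residual, x$U_target))
  invisible(x)
}

#' Two-spring fixator/callus load-sharing model
#'
#' Lumped surrogate for the coarse bone-fixator model: the axial load is
#' shared between the external fixator and the callus, so the interface
#' closing displacement is `u = F_axial / (k_fixator + k_callus)`.
#'
#' @param k_fixator Axial fixator stiffness, N/mm (default 50, a
#'   configuration placeholder for the unpublished fixator calibration).
#' @param k_callus Callus axial stiffness, N/mm (from [axial_stiffness()]).
#' @param defect_length Defect length, mm (metadata).
#' @return An object of class `spring_model`.
#' @export
spring_model <- function(k_fixator = 50, k_callus, defect_length = NA_real_) {
  if (k_fixator <= 0 || k_callus <= 0)
    stop("spring stiffnesses must be positive")
  structure(list(k_fixator = k_fixator, k_callus = k_callus,
                 defect_length = defect_length),
            class = "spring_model")
}

#' Image-edge boundary displacements from an estimated load
#'
#' Translates the organ-scale axial load into micro-FE boundary conditions:
#' the interface closing displacement `u = F_axial / (k_fixator +
#' k_callus)` is applied as equal-and-opposite axial displacements on the
#' two axial image faces. The bending contribution is off by default; if
#' enabled it adds a linear axial-displacement gradient across the face.
#'
#' @param estimate A `load_estimate`.
#' @param spring A [spring_model()].
#' @param dims Element grid dimensions.
#' @param voxel_size Voxel edge, micrometres.
#' @param bending_theta Optional face rotation (radians) transferring the
#'   bending moment; default NULL (omitted).
#' @return A `bc_spec`, plus attribute `closure` (mm).
#' @export
boundary_displacements <- function(estimate, spring, dims, voxel_size,
                                   bending_theta = NULL) {
  ksum <- spring$k_fixator + spring$k_callus
  if (!is.finite(ksum) || ksum <= 0) stop("non-positive stiffness sum")
  u <- estimate$F_axial / ksum
  bc <- bc_axial(as.integer(dims), voxel_size, closure = u)
  if (!is.null(bending_theta)) {
    bb <- bc_axial_bending(as.integer(dims), voxel_size, bending_theta)
    dofs <- c(bc$dofs, bb$dofs)
    vals <- c(bc$values, bb$values)
    agg <- tapply(vals, dofs, sum)
    bc <- new_bc_spec(as.integer(names(agg)), as.numeric(agg),
                      as.integer(dims), "axial closure + bending gradient")
  }
  attr(bc, "closure") <- u
  bc
}
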