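#' Boundary-condition specification for the voxel FE problem
#'
#' The default reproduces the compressive protocol: the bottom slice of nodes
#' is fully fixed and the top slice is displaced axially by 1% of the domain
#' length (`delta = 0.01`), transverse components free. The `roller` bottom
#' mode (axial fix only, plus minimal rigid-body pins) exists for closed-form
#' validation: with roller support a homogeneous block is in uniform uniaxial
#' stress, so every element sees exactly `delta` effective strain.
#'
#' @param delta Axial compressive displacement as a fraction of the domain
#'   axial length (0 < delta < 0.1; default 0.01, i.e. 1%).
#' @param bottom `"full-fix"` (default) or `"roller"`.
#' @param top Transverse constraint of the displaced top slice: `"free"`
#'   (default) or `"fixed"`.
#' @return A `bc_spec` object.
#' @export
bc_spec <- function(delta = 0.01, bottom = c("full-fix", "roller"),
                    top = c("free", "fixed")) {
  if (!is.finite(delta) || delta < 0 || delta >= 0.1) {
    stop("`delta` must lie in [0, 0.1)", call. = FALSE)
  }
  structure(list(delta = delta, bottom = match.arg(bottom),
                 top = match.arg(top)),
            class = "bc_spec")
}

#' Stiffness matrix of a trilinear hexahedral voxel element
#'
#' 8-node brick with isotropic linear elasticity, integrated with 2x2x2 Gauss
#' quadrature. Corner order is lexicographic in (x, y, z) with x fastest. The
#' matrix is symmetric positive semi-definite with exactly six zero
#' eigenvalues (rigid-body modes), scales linearly in `E` and linearly in the
#' edge length `h`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio (0 < nu < 0.5).
#' @param h Voxel edge length (mm).
#' @return A 24 x 24 numeric matrix (N/mm per mm of displacement).
#' @export
element_stiffness <- function(E, nu = 0.3, h = 0.0105) {
  if (!is.finite(E) || E <= 0) stop("`E` must be > 0", call. = FALSE)
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5) {
    stop("`nu` must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.finite(h) || h <= 0) stop("`h` must be > 0", call. = FALSE)

  # natural corner coordinates, x fastest
  corners <- as.matrix(expand.grid(xi = c(-1, 1), eta = c(-1, 1),
                                   zeta = c(-1, 1)))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu

  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (gx in gp) for (gy in gp) for (gz in gp) {
    # shape-function gradients in natural coords, then physical (chain rule
    # with J = (h/2) I)
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      cx <- corners[a, 1]; cy <- corners[a, 2]; cz <- corners[a, 3]
      dN[a, ] <- c(cx * (1 + cy * gy) * (1 + cz * gz),
                   (1 + cx * gx) * cy * (1 + cz * gz),
                   (1 + cx * gx) * (1 + cy * gy) * cz) / 8 * (2 / h)
    }
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# Flood-fill reachability through stiff (bone or cap) elements with
# 6-connectivity: does a load path connect bottom and top faces?
stiff_path_connected <- function(stiff) {
  d <- dim(stiff)
  reach <- array(FALSE, d)
  reach[, , 1] <- stiff[, , 1]
  if (!any(reach)) return(FALSE)
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & stiff
    if (any(grown[, , d[3]])) return(TRUE)
    if (identical(grown, reach)) return(FALSE)
    reach <- grown
  }
}

#' Solve the voxel micro-FE compression problem
#'
#' Builds the linear hexahedral problem from a `material_volume` (every voxel
#' is one element; soft tissue is retained at its low modulus), applies the
#' displacement boundary conditions, and solves the SPD system with
#' matrix-free Jacobi-preconditioned conjugate gradients. Per-element strain
#' energy density `U` and effective strain `sqrt(2 U / E)` are evaluated at
#' the element level, and the resultant force is the sum of axial nodal
#' reactions on the top surface.
#'
#' Internally the unit system is mm / MPa / N, so reaction forces come out in
#' newtons directly; strains are reported in microstrain.
#'
#' @param matvol A `material_volume` from [build_material_volume()].
#' @param bc A [bc_spec()].
#' @param tol Relative-residual convergence tolerance (default 1e-6).
#' @param maxit Iteration cap; default `10 * sqrt(n_dof)` rounded up.
#' @param warm_start Optional displacement vector from a previous solve on the
#'   same grid, used as the initial iterate.
#' @return An `fe_solution`: displacement array (`n_nodes x 3`), per-element
#'   strain energy density (MPa) and effective strain (microstrain) arrays,
#'   `f_resultant` (N), reaction sums, and a convergence report.
#' @examples
#' \donttest{
#' blk <- make_homogeneous_block(c(4, 4, 4), 500)
#' mv <- build_material_volume(blk, cap = "none")
#' sol <- solve_microfe(mv, bc_spec(bottom = "roller"))
#' sol$f_resultant
#' }
#' @export
solve_microfe <- function(matvol, bc = bc_spec(), tol = 1e-6, maxit = NULL,
                          warm_start = NULL) {
  if (!inherits(matvol, "material_volume")) {
    stop("expected a `material_volume`", call. = FALSE)
  }
  if (!inherits(bc, "bc_spec")) stop("expected a `bc_spec`", call. = FALSE)
  d <- dim(matvol)
  h <- matvol$voxel_size
  E_mpa <- matvol$modulus * 1000  # GPa -> MPa
  if (any(E_mpa <= 0)) stop("all element moduli must be > 0", call. = FALSE)

  stiff <- matvol$role != role_codes[["soft"]]
  connected <- stiff_path_connected(stiff)
  if (!connected) {
    warning("no bone/cap load path connects top and bottom faces; ",
            "load is carried by soft tissue only", call. = FALSE)
  }

  nn <- d + 1L
  n_nodes <- prod(nn)
  ndof <- 3L * n_nodes
  if (is.null(maxit)) maxit <- ceiling(10 * sqrt(ndof))

  Lz <- d[3L] * h
  uz_top <- -bc$delta * Lz

  # node (i,j,k) -> id = i + nnx*(j + nny*k), 0-based; dof = 3*id + comp
  kz <- rep(seq_len(nn[3]), each = nn[1] * nn[2])  # axial layer per node
  bottom <- kz == 1L
  top <- kz == nn[3]

  fixed <- logical(ndof)
  u0 <- numeric(ndof)
  zdof <- function(nodes) 3L * (which(nodes) - 1L) + 3L
  xdof <- function(nodes) 3L * (which(nodes) - 1L) + 1L
  ydof <- function(nodes) 3L * (which(nodes) - 1L) + 2L

  fixed[zdof(bottom)] <- TRUE
  if (bc$bottom == "full-fix") {
    fixed[xdof(bottom)] <- TRUE
    fixed[ydof(bottom)] <- TRUE
  } else {
    # rigid-body pins consistent with uniform uniaxial stress: node (1,1,1)
    # in x and y, node (nnx,1,1) in y (kills rotation about z)
    pin1 <- 1L
    pin2 <- nn[1]
    fixed[3L * (pin1 - 1L) + 1:2] <- TRUE
    fixed[3L * (pin2 - 1L) + 2L] <- TRUE
  }
  fixed[zdof(top)] <- TRUE
  u0[zdof(top)] <- uz_top
  if (bc$top == "fixed") {
    fixed[xdof(top)] <- TRUE
    fixed[ydof(top)] <- TRUE
  }

  # ramp initial guess: linear axial compression profile
  if (is.null(warm_start)) {
    u_init <- numeric(ndof)
    u_init[3L * (seq_len(n_nodes) - 1L) + 3L] <-
      uz_top * (kz - 1L) / (nn[3] - 1L)
  } else {
    stopifnot(length(warm_start) == ndof)
    u_init <- warm_start
  }
  u_init[fixed] <- u0[fixed]

  Kref <- element_stiffness(1, matvol$nu, h)  # unit modulus, scaled per element
  res <- .cg_solve_voxel(as.vector(E_mpa), as.integer(d), Kref, fixed, u_init,
                         tol, as.integer(maxit))
  if (!res$converged && bc$delta > 0) {
    stop("micro-FE solver did not converge in ", res$iterations,
         " iterations (relative residual ", signif(res$relres, 3), ")",
         call. = FALSE)
  }

  w <- array(res$energy, d)                 # N*mm per element
  sed <- w / h^3                            # MPa
  eff <- sqrt(2 * sed / E_mpa) * 1e6        # microstrain
  fz <- res$f[3L * (seq_len(n_nodes) - 1L) + 3L]
  f_top <- sum(fz[top])
  f_bottom <- sum(fz[bottom])
  f_resultant <- abs(f_top)

  structure(
    list(
      displacement = matrix(res$u, ncol = 3L, byrow = TRUE),
      sed = sed,
      eff_strain = eff,
      f_resultant = f_resultant,
      f_top = f_top,
      f_bottom = f_bottom,
      delta = bc$delta,
      voxel_size = h,
      dims = d,
      bc = bc,
      connected = connected,
      convergence = list(iterations = res$iterations, relres = res$relres,
                         converged = res$converged,
                         history = res$history)
    ),
    class = "fe_solution"
  )
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(
    "<fe_solution> %d x %d x %d elements, delta = %g\n", x$dims[1], x$dims[2],
    x$dims[3], x$delta))
  cat(sprintf("  F_resultant = %.4g N (top %.4g, bottom %.4g)\n",
              x$f_resultant, x$f_top, x$f_bottom))
  cat(sprintf("  CG: %d iterations, relative residual %.2e\n",
              x$convergence$iterations, x$convergence$relres))
  invisible(x)
}

#' Extract the bone-tissue effective-strain distribution
#'
#' Collects the per-element effective strains over the masked (bone) elements
#' into a [strain_distribution()] — the "mechanical environment" — carrying
#' the simulation's resultant force. Strains are initially expressed at an
#' applied force equal to `F_resultant`; rescale with [scale_strains()].
#'
#' @param solution An `fe_solution` from [solve_microfe()].
#' @param mask Logical array matching the element grid (e.g. [bone_mask()]).
#' @param provenance Optional free-form provenance list (volume id, week, ...).
#' @return A [strain_distribution()].
#' @export
effective_strain_field <- function(solution, mask, provenance = list()) {
  if (!inherits(solution, "fe_solution")) {
    stop("expected an `fe_solution`", call. = FALSE)
  }
  if (!identical(dim(mask), as.integer(solution$dims)) &&
      !identical(dim(mask), solution$dims)) {
    stop("mask shape does not match the element grid", call. = FALSE)
  }
  values <- solution$eff_strain[mask]
  if (length(values) == 0L) {
    stop("mask selects no elements: empty strain distribution", call. = FALSE)
  }
  strain_distribution(values, f_resultant = solution$f_resultant,
                      f_applied = solution$f_resultant,
                      provenance = provenance)
}
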