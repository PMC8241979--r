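# Independent oracles used across the suite. These deliberately take the
# slow, explicit route (dense assembly, exhaustive grids, array flood fill)
# so they share no code path with the solver and adaptation internals.

# Dense global stiffness assembly for tiny grids: same node numbering as the
# solver (node id = i + nnx*(j + nny*k), zero-based; corner order x-fastest),
# but built entry by entry in R and solved with base::solve().
assemble_dense_K <- function(E_mpa, nu, h) {
  d <- dim(E_mpa)
  nn <- d + 1L
  ndof <- 3L * prod(nn)
  node_id <- function(i, j, k) i + nn[1] * (j + nn[2] * k)  # 0-based
  corners <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  Kref <- element_stiffness(1, nu, h)
  K <- matrix(0, ndof, ndof)
  for (k in seq_len(d[3]) - 1L) {
    for (j in seq_len(d[2]) - 1L) {
      for (i in seq_len(d[1]) - 1L) {
        ids <- node_id(i + corners[, 1], j + corners[, 2], k + corners[, 3])
        dofs <- as.vector(t(outer(ids, 0:2, function(a, b) 3L * a + b))) + 1L
        K[dofs, dofs] <- K[dofs, dofs] + E_mpa[i + 1, j + 1, k + 1] * Kref
      }
    }
  }
  K
}

# Direct dense solve of the constrained problem; returns full displacement.
dense_solve <- function(E_mpa, nu, h, fixed, u_fix) {
  K <- assemble_dense_K(E_mpa, nu, h)
  free <- !fixed
  rhs <- -K[free, fixed, drop = FALSE] %*% u_fix[fixed]
  u <- u_fix
  u[free] <- solve(K[free, free], rhs)
  u
}

# Boundary conditions mirroring solve_microfe's default full-fix setup, built
# independently for the dense oracle.
dense_bcs <- function(d, h, delta) {
  nn <- d + 1L
  n_nodes <- prod(nn)
  kz <- rep(seq_len(nn[3]), each = nn[1] * nn[2])
  fixed <- logical(3L * n_nodes)
  u_fix <- numeric(3L * n_nodes)
  bottom <- which(kz == 1L); top <- which(kz == nn[3])
  for (c in 1:3) fixed[3L * (bottom - 1L) + c] <- TRUE
  fixed[3L * (top - 1L) + 3L] <- TRUE
  u_fix[3L * (top - 1L) + 3L] <- -delta * d[3] * h
  list(fixed = fixed, u_fix = u_fix)
}

# material_volume built directly (bypasses the density ladder) for solver
# tests that need arbitrary moduli
raw_material_volume <- function(E_gpa, voxel_size, nu = 0.3,
                                role = NULL) {
  if (is.null(role)) {
    role <- array(rtfe::role_codes[["bone"]], dim(E_gpa))
  }
  structure(list(modulus = E_gpa, role = role, voxel_size = voxel_size,
                 nu = nu, model = NULL, metadata = list()),
            class = "material_volume")
}

# 26-connected reachability from the first to the last axial slice of a
# logical mask, by iterative dilation (independent of any package internals).
reaches_top_26 <- function(mask) {
  d <- dim(mask)
  shift <- function(a, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
    out
  }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  reach <- array(FALSE, d)
  reach[, , 1] <- mask[, , 1]
  repeat {
    grown <- reach
    for (r in seq_len(nrow(offs))) {
      grown <- grown | shift(reach, offs$dx[r], offs$dy[r], offs$dz[r])
    }
    grown <- grown & mask
    if (any(grown[, , d[3]])) return(TRUE)
    if (identical(grown, reach)) return(FALSE)
    reach <- grown
  }
}

# Exhaustive grid-search oracle for the KS load matching: evaluates D on a
# fine force grid and returns the best force and D.
grid_search_load <- function(dist, target, lo, hi, n = 2000) {
  fs <- seq(lo, hi, length.out = n)
  ds <- vapply(fs, function(f) {
    ks_statistic(dist$values * (f / dist$f_applied), target$values)
  }, 0)
  list(force = fs[which.min(ds)], ks = min(ds), forces = fs, ds = ds)
}

# The overloaded-strut phantom embeds a desk-scale FE solve; generate it once
# per test run and share it.
overloaded_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_overloaded_strut_phantom()
    cache
  }
})

# a bare load plan at a given matched force, for guard-only tests
new_plan_at <- function(f) {
  rtfe:::new_load_plan(f_matched = f, ks = 0.1, converged = TRUE,
                       evaluations = 1L,
                       trace = tibble::tibble(eval = 1L, force = f, ks = 0.1),
                       f0 = f)
}
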