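#' Multi-density material model
#'
#' The density-to-stiffness mapping used for voxel micro-FE of mineralizing
#' bone: densities from 395 to 720 mg HA/cm^3, in steps of 25 mg HA/cm^3 (14
#' levels), map to linearly spaced Young's moduli from 4.045 to 12.170 GPa (a
#' ladder increment of exactly (12.170 - 4.045)/13 = 0.625 GPa). Voxels below
#' the density floor are soft tissue at 0.003 GPa; the medullary cavity at the
#' loaded end is capped with a stiff 20 GPa plate to prevent edge effects.
#' Poisson's ratio is a single global constant for all phases.
#'
#' @param rho_min,rho_max Density floor and ceiling of the bone ladder
#'   (mg HA/cm^3).
#' @param rho_step Ladder spacing (mg HA/cm^3); `(rho_max - rho_min)/rho_step`
#'   must be an integer.
#' @param E_min,E_max Moduli at the floor and ceiling (GPa).
#' @param E_soft Soft-tissue modulus (GPa).
#' @param E_cap Marrow-cap plate modulus (GPa).
#' @param nu Poisson's ratio, shared by all phases (0 < nu < 0.5). 0.3 is the
#'   standard choice in this micro-FE literature.
#' @param quantization `"floor"` (default) assigns the ladder level at or
#'   below the density; `"round"` assigns the nearest level.
#' @return A `material_model` object.
#' @examples
#' m <- material_model()
#' density_to_modulus(c(100, 395, 420, 720, 1000), m)
#' @export
material_model <- function(rho_min = 395, rho_max = 720, rho_step = 25,
                           E_min = 4.045, E_max = 12.170,
                           E_soft = 0.003, E_cap = 20, nu = 0.3,
                           quantization = c("floor", "round")) {
  quantization <- match.arg(quantization)
  n_steps <- (rho_max - rho_min) / rho_step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("(rho_max - rho_min) must be an integer multiple of rho_step",
         call. = FALSE)
  }
  n_steps <- as.integer(round(n_steps))
  if (!(E_soft < E_min && E_min < E_max && E_max < E_cap)) {
    stop("moduli must satisfy E_soft < E_min < E_max < E_cap", call. = FALSE)
  }
  if (!(nu > 0 && nu < 0.5)) stop("need 0 < nu < 0.5", call. = FALSE)
  structure(
    list(rho_min = rho_min, rho_max = rho_max, rho_step = rho_step,
         E_min = E_min, E_max = E_max, E_soft = E_soft, E_cap = E_cap,
         nu = nu, n_steps = n_steps, quantization = quantization),
    class = "material_model"
  )
}

#' Ladder of bone moduli
#'
#' @param model A [material_model()].
#' @return Numeric vector of the bone Young's moduli (GPa), one per density
#'   level, strictly increasing.
#' @export
modulus_ladder <- function(model = material_model()) {
  lad <- model$E_min +
    (0:model$n_steps) * (model$E_max - model$E_min) / model$n_steps
  lad[model$n_steps + 1] <- model$E_max  # endpoint exact to the last bit
  lad
}

#' Map mineral density to Young's modulus and tissue role
#'
#' Densities below the ladder floor are soft tissue; densities at or above the
#' floor are quantized to a ladder level (floor rule by default: 395-419.99
#' maps to level 0, and so on), clamped to the ceiling, and assigned the
#' linearly spaced modulus for that level.
#'
#' @param density Numeric vector/array of densities (mg HA/cm^3), finite and
#'   non-negative.
#' @param model A [material_model()].
#' @return A list with `modulus` (GPa, same shape as `density`) and `role`
#'   (integer codes: 1 bone, 2 soft; see [role_codes]).
#' @export
density_to_modulus <- function(density, model = material_model()) {
  if (anyNA(density) || any(!is.finite(density)) || any(density < 0)) {
    stop("densities must be finite and >= 0", call. = FALSE)
  }
  ladder <- modulus_ladder(model)
  lvl <- (density - model$rho_min) / model$rho_step
  lvl <- if (model$quantization == "floor") floor(lvl) else round(lvl)
  lvl <- pmin(pmax(lvl, 0), model$n_steps)
  soft <- density < model$rho_min
  modulus <- ladder[lvl + 1]
  modulus[soft] <- model$E_soft
  role <- array(role_codes[["bone"]], dim = dim(density) %||% length(density))
  role[soft] <- role_codes[["soft"]]
  if (!is.null(dim(density))) dim(modulus) <- dim(density)
  list(modulus = modulus, role = role)
}

#' Tissue role codes used in material volumes
#'
#' Integer labels of the per-voxel role array: bone (on the modulus ladder),
#' soft tissue, and the marrow-cap plate.
#' @format Named integer vector.
#' @export
role_codes <- c(bone = 1L, soft = 2L, cap = 3L)

#' Per-voxel material volume
#'
#' Applies [density_to_modulus()] voxel-wise and then caps the marrow cavity
#' at the loaded (top) end with a stiff plate (see [add_marrow_cap()]).
#'
#' @param vol A [density_volume()].
#' @param model A [material_model()].
#' @param cap `"top"` (default) caps the last axial slice, `"both"` caps both
#'   end slices, `"none"` skips capping.
#' @return A `material_volume` object: `modulus` (GPa array), `role` (integer
#'   array of [role_codes]), `voxel_size`, `nu`, `model`, `metadata`.
#' @export
build_material_volume <- function(vol, model = material_model(),
                                  cap = c("top", "both", "none")) {
  assert_volume(vol)
  cap <- match.arg(cap)
  dm <- density_to_modulus(vol$values, model)
  mv <- structure(
    list(modulus = dm$modulus, role = dm$role, voxel_size = vol$voxel_size,
         nu = model$nu, model = model, metadata = vol$metadata),
    class = "material_volume"
  )
  if (cap != "none") mv <- add_marrow_cap(mv, model, which = cap)
  mv
}

#' @export
dim.material_volume <- function(x) dim(x$modulus)

#' @export
print.material_volume <- function(x, ...) {
  d <- dim(x)
  tab <- table(factor(x$role, levels = role_codes, labels = names(role_codes)))
  cat(sprintf("<material_volume> %d x %d x %d elements @ %.4g mm, nu = %.2f\n",
              d[1], d[2], d[3], x$voxel_size, x$nu))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Point-in-convex-hull test: half-plane checks against the hull polygon
# (counter-clockwise order from grDevices::chull reversed as needed).
in_convex_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  if (n < 3L) return(rep(FALSE, length(px)))
  # ensure counter-clockwise orientation via the shoelace sum
  area2 <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= 0
  }
  inside
}

#' Cap the marrow cavity with a stiff plate
#'
#' Soft-tissue voxels on an end slice that lie inside the transverse convex
#' hull of that slice's bone voxels are relabeled as a 20 GPa cap plate. The
#' plate closes the medullary canal so the prescribed axial displacement is
#' not absorbed by soft tissue at the mesh boundary; cap voxels are excluded
#' from every strain analysis mask.
#'
#' @param matvol A `material_volume`.
#' @param model A [material_model()] supplying `E_cap`.
#' @param which `"top"` (last axial slice) or `"both"` end slices.
#' @return The capped `material_volume`.
#' @export
add_marrow_cap <- function(matvol, model = matvol$model %||% material_model(),
                           which = c("top", "both")) {
  which <- match.arg(which)
  d <- dim(matvol)
  if (d[3L] < 3L) stop("need at least 3 axial slices to cap", call. = FALSE)
  slices <- if (which == "both") c(d[3L], 1L) else d[3L]
  for (k in slices) {
    role_k <- matvol$role[, , k]
    bone <- which(role_k == role_codes[["bone"]], arr.ind = TRUE)
    if (nrow(bone) < 3L) next
    hull <- grDevices::chull(bone[, 1], bone[, 2])
    soft <- which(role_k == role_codes[["soft"]], arr.ind = TRUE)
    if (nrow(soft) == 0L) next
    inside <- in_convex_hull(soft[, 1], soft[, 2],
                             bone[hull, 1], bone[hull, 2])
    sel <- soft[inside, , drop = FALSE]
    if (nrow(sel)) {
      role_k[sel] <- role_codes[["cap"]]
      mod_k <- matvol$modulus[, , k]
      mod_k[sel] <- model$E_cap
      matvol$role[, , k] <- role_k
      matvol$modulus[, , k] <- mod_k
    }
  }
  matvol$metadata$cap <- which
  matvol
}

#' Bone analysis mask
#'
#' Logical mask that is `TRUE` exactly where the voxel role is bone; soft
#' tissue and the marrow cap are excluded, so strain analysis runs on bone
#' tissue only. Mask cardinality times the voxel volume is the bone volume
#' used for BV/BV0 reporting.
#'
#' @param matvol A `material_volume`.
#' @return Logical 3-D array.
#' @export
bone_mask <- function(matvol) {
  if (!inherits(matvol, "material_volume")) {
    stop("expected a `material_volume`", call. = FALSE)
  }
  matvol$role == role_codes[["bone"]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
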