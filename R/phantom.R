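#' Specification of a synthetic osteotomized-femur phantom
#'
#' Describes a hollow cylindrical cortical shaft aligned with the axial (z)
#' axis, interrupted by a transverse osteotomy gap that may be bridged by thin
#' mineralizing callus struts, embedded in soft tissue with additive Gaussian
#' density noise (truncated at 0). The phantom stands in for registered
#' micro-CT segments of a femoral defect between fixation screws. Densities
#' are generated directly in mg HA/cm^3 (no scanner grayscale calibration).
#'
#' The desk-scale default grid is 48 x 48 x 60 voxels so a full FE solve stays
#' interactive on one CPU; the full-scale 300 x 300 x 210 geometry is
#' supported by passing `shape`. The default voxel size scales with the grid
#' (`0.0105 * 300 / shape[1]` mm) so every phantom represents the same
#' 3.15 mm femoral segment: a coarser grid is the same bone imaged at lower
#' resolution, not a miniature. Forces therefore stay in the newton regime of
#' in vivo loading at any grid, and at 300 x 300 x 210 the voxel size is the
#' native 10.5 micrometres.
#'
#' @param shape Grid shape (x, y, z) in voxels.
#' @param voxel_size Voxel edge (mm); `NULL` (default) uses
#'   `0.0105 * 300 / shape[1]`.
#' @param cortex_radius Outer cortical radius (voxels).
#' @param cortex_thickness Cortical wall thickness (voxels).
#' @param gap_width Osteotomy gap width (axial slices).
#' @param cortex_density,callus_density Densities (mg HA/cm^3); must be at or
#'   above the 395 bone threshold.
#' @param strut_count Number of bridging callus struts (0 for an unbridged
#'   defect).
#' @param strut_radius Strut radius (voxels); must be smaller than
#'   `cortex_radius`.
#' @param bridge_fraction Fraction (0-1) of the cortical footprint inside the
#'   gap that is filled with porous bridging callus; the fill pattern is a
#'   seeded per-column lottery, so increasing the fraction strictly grows the
#'   fill (mineralizing woven bone).
#' @param collar_radius Thickness (voxels) of a periosteal callus collar
#'   around the cortex near the gap (0 disables it); the collar adds
#'   load-bearing area the way external callus does in vivo.
#' @param collar_span Axial half-extent of the collar beyond the gap
#'   (slices).
#' @param background_density Soft-tissue density (mg HA/cm^3), below 395.
#' @param noise_sd Additive Gaussian density noise SD (mg HA/cm^3).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   volume.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 60L), voxel_size = NULL,
                         cortex_radius = 14, cortex_thickness = 4,
                         gap_width = 8L, cortex_density = 700,
                         callus_density = 500, strut_count = 3L,
                         strut_radius = 2, bridge_fraction = 0.35,
                         collar_radius = 0, collar_span = 8L,
                         background_density = 100,
                         noise_sd = 15, seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) {
    stop("`shape` must be 3 positive extents (>= 2 voxels each)", call. = FALSE)
  }
  if (is.null(voxel_size)) voxel_size <- 0.0105 * 300 / shape[1]
  if (!is.finite(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be > 0", call. = FALSE)
  }
  geom <- c(cortex_radius = cortex_radius, cortex_thickness = cortex_thickness,
            gap_width = gap_width, strut_radius = strut_radius)
  if (any(!is.finite(geom)) || any(geom[c(1, 2, 3)] <= 0) || strut_radius <= 0) {
    stop("geometric dimensions must be strictly positive", call. = FALSE)
  }
  if (2 * cortex_radius >= min(shape[1:2]) || gap_width >= shape[3]) {
    stop("geometry does not fit inside the grid", call. = FALSE)
  }
  if (strut_radius >= cortex_radius) {
    stop("strut radius must be smaller than the cortex radius", call. = FALSE)
  }
  if (cortex_density < 395 || callus_density < 395) {
    stop("cortex/callus densities must be at or above 395 mg HA/cm^3",
         call. = FALSE)
  }
  if (background_density >= 395 || background_density < 0) {
    stop("background density must lie in [0, 395)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (bridge_fraction < 0 || bridge_fraction > 1) {
    stop("`bridge_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (collar_radius < 0 ||
      cortex_radius + collar_radius >= min(shape[1:2]) / 2) {
    stop("collar does not fit inside the grid", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = voxel_size,
         cortex_radius = cortex_radius, cortex_thickness = cortex_thickness,
         gap_width = as.integer(gap_width),
         cortex_density = cortex_density, callus_density = callus_density,
         strut_count = as.integer(strut_count), strut_radius = strut_radius,
         bridge_fraction = bridge_fraction, collar_radius = collar_radius,
         collar_span = as.integer(collar_span),
         background_density = background_density, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched
with_phantom_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Homogeneous density block
#'
#' A constant-density rectangular volume — the basic oracle fixture for the
#' FE solver (uniform material, closed-form uniaxial answer under roller
#' support).
#'
#' @param shape Grid shape (x, y, z), each >= 2.
#' @param density Density (mg HA/cm^3), >= 0.
#' @param voxel_size Voxel edge (mm).
#' @return A [density_volume()].
#' @export
make_homogeneous_block <- function(shape, density, voxel_size = 0.0105) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) {
    stop("`shape` must be 3 extents of at least 2 voxels", call. = FALSE)
  }
  if (!is.finite(density) || density < 0) {
    stop("`density` must be >= 0", call. = FALSE)
  }
  density_volume(array(density, shape), voxel_size,
                 metadata = list(phantom = "homogeneous_block"))
}

# angular strut positions: evenly spaced with seeded jitter (reproducible yet
# varied cohorts)
strut_angles <- function(n, jitter_sd = 0.15) {
  base <- 2 * pi * (seq_len(n) - 1) / n
  base + stats::rnorm(n, sd = jitter_sd)
}

#' Generate an osteotomized-femur phantom
#'
#' Builds the density volume described by a [phantom_spec()] together with
#' ground-truth masks: `cortex`, `callus` (struts), `background`, and the
#' axial `gap` region. The three tissue masks are disjoint and cover the
#' grid. Struts span the gap and extend two slices into each cortical
#' fragment so bridged phantoms are mechanically connected.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [density_volume()]), `masks` (list of
#'   logical arrays), and `spec`.
#' @export
make_osteotomy_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) {
    stop("expected a `phantom_spec`", call. = FALSE)
  }
  d <- spec$shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xy <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  r <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
  ring <- r <= spec$cortex_radius & r > spec$cortex_radius - spec$cortex_thickness
  ring <- matrix(ring, d[1], d[2])

  gap_lo <- floor((d[3] - spec$gap_width) / 2) + 1L
  gap_hi <- gap_lo + spec$gap_width - 1L
  gap_slices <- seq.int(gap_lo, gap_hi)

  cortex <- array(FALSE, d)
  for (k in seq_len(d[3])) if (!(k %in% gap_slices)) cortex[, , k] <- ring

  callus <- array(FALSE, d)
  with_phantom_rng(spec$seed, {
    # per-column porosity lottery, drawn first and independent of geometry so
    # the fill pattern is shared (and therefore nested) across a healing
    # series generated from the same seed
    u_plane <- matrix(stats::runif(d[1] * d[2]), d[1], d[2])

    # porous bridging callus on the cortical footprint inside the gap
    if (spec$bridge_fraction > 0) {
      fill <- ring & u_plane < spec$bridge_fraction
      for (k in gap_slices) callus[, , k] <- callus[, , k] | fill
    }

    # periosteal collar around the gap region
    if (spec$collar_radius > 0) {
      collar_ring <- r <= spec$cortex_radius + spec$collar_radius &
        r > spec$cortex_radius
      collar_ring <- matrix(collar_ring, d[1], d[2]) &
        u_plane < max(spec$bridge_fraction, 0.5)
      span <- seq.int(max(1L, gap_lo - spec$collar_span),
                      min(d[3], gap_hi + spec$collar_span))
      for (k in span) callus[, , k] <- callus[, , k] | collar_ring
    }

    # discrete bridging struts, two slices of anchorage into each fragment
    if (spec$strut_count > 0L) {
      ang <- strut_angles(spec$strut_count)
      r_mid <- spec$cortex_radius - spec$cortex_thickness / 2
      strut_slices <- seq.int(max(1L, gap_lo - 2L), min(d[3], gap_hi + 2L))
      for (a in ang) {
        sx <- cx + r_mid * cos(a); sy <- cy + r_mid * sin(a)
        disc <- (xy$x - sx)^2 + (xy$y - sy)^2 <= spec$strut_radius^2
        disc <- matrix(disc, d[1], d[2])
        for (k in strut_slices) callus[, , k] <- callus[, , k] | disc
      }
    }
    callus <- callus & !cortex
    vals <- array(spec$background_density, d)
    vals[cortex] <- spec$cortex_density
    vals[callus] <- spec$callus_density
    if (spec$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), sd = spec$noise_sd)
    }
    vals[vals < 0] <- 0
  })

  gap_mask <- array(FALSE, d)
  gap_mask[, , gap_slices] <- TRUE
  masks <- list(cortex = cortex, callus = callus,
                background = !cortex & !callus, gap = gap_mask)
  vol <- density_volume(vals, spec$voxel_size,
                        metadata = list(phantom = "osteotomy", seed = spec$seed,
                                        spec = unclass(spec)))
  list(volume = vol, masks = masks, spec = spec)
}

#' Specification of a longitudinal healing series
#'
#' A weekly sequence of phantoms on a shared (registered) grid.
#' Formation-like series emulate loaded-group healing: struts thicken and
#' mineralize week over week, eventually coalescing toward a bridging wall,
#' so bone voxel count is non-decreasing. Resorption-like series emulate
#' control-group remodelling: the cortical wall and struts thin, so bone
#' voxel count is non-increasing.
#'
#' @param base A [phantom_spec()] describing week 0.
#' @param n_time Number of weekly time points (>= 2; default 5).
#' @param mode `"formation"` or `"resorption"`.
#' @param strut_growth Weekly strut radius increment (voxels) in formation
#'   mode.
#' @param density_rate Weekly callus density increment (mg HA/cm^3) in
#'   formation mode.
#' @param bridging_rate Weekly change of the porous bridge fill fraction
#'   (added in formation mode, removed in resorption mode).
#' @param collar_growth Weekly periosteal collar growth (voxels) in formation
#'   mode.
#' @param thinning Weekly cortical/strut thinning (voxels) in resorption mode.
#' @return A `healing_series_spec` object.
#' @export
healing_series_spec <- function(base = phantom_spec(), n_time = 5L,
                                mode = c("formation", "resorption"),
                                strut_growth = 0.5, density_rate = 30,
                                bridging_rate = 0.15, collar_growth = 0.75,
                                thinning = 0.4) {
  mode <- match.arg(mode)
  n_time <- as.integer(n_time)
  if (n_time < 2L) stop("a healing series needs at least 2 time points",
                        call. = FALSE)
  if (mode == "resorption") {
    last_thickness <- base$cortex_thickness - (n_time - 1L) * thinning
    if (last_thickness < 1) {
      stop("thinning rate would consume the cortex within the series",
           call. = FALSE)
    }
  }
  structure(list(base = base, n_time = n_time, mode = mode,
                 strut_growth = strut_growth, density_rate = density_rate,
                 bridging_rate = bridging_rate, collar_growth = collar_growth,
                 thinning = thinning),
            class = "healing_series_spec")
}

#' Generate a longitudinal healing series
#'
#' All time points share the grid (registration frame) and the noise field
#' (the phantom seed), so geometric change is the only difference between
#' weeks and the stated monotonicity of bone voxel count holds by
#' construction.
#'
#' @param spec A [healing_series_spec()].
#' @return A list of phantom results (as from [make_osteotomy_phantom()]),
#'   one per week, each with `week` recorded in the volume metadata.
#' @export
make_healing_series <- function(spec) {
  if (!inherits(spec, "healing_series_spec")) {
    stop("expected a `healing_series_spec`", call. = FALSE)
  }
  base <- spec$base
  out <- vector("list", spec$n_time)
  for (t in seq_len(spec$n_time)) {
    wk <- t - 1L
    sp <- base
    if (spec$mode == "formation") {
      sp$strut_radius <- min(base$strut_radius + wk * spec$strut_growth,
                             base$cortex_radius - 0.5)
      sp$callus_density <- min(base$callus_density + wk * spec$density_rate, 720)
      sp$bridge_fraction <- min(base$bridge_fraction + wk * spec$bridging_rate,
                                0.95)
      collar_max <- floor(min(base$shape[1:2]) / 2) - base$cortex_radius - 1
      sp$collar_radius <- min(base$collar_radius + wk * spec$collar_growth,
                              collar_max)
    } else {
      sp$cortex_thickness <- base$cortex_thickness - wk * spec$thinning
      sp$strut_radius <- max(base$strut_radius - wk * spec$thinning, 0.8)
      sp$bridge_fraction <- max(base$bridge_fraction - wk * spec$bridging_rate,
                                0.05)
    }
    ph <- make_osteotomy_phantom(sp)
    ph$volume$metadata$week <- wk
    ph$week <- wk
    out[[t]] <- ph
  }
  out
}

#' Generate a deliberately over-strained single-strut phantom
#'
#' A defect bridged by one thin, weakly mineralized strut: the configuration
#' in which many highly strained voxels sit next to one another in the
#' callus. At the documented reference load more than 50 bone voxels are at
#' or above 10,000 microstrain — verified at generation time by running the
#' micro-FE solver — so the phantom reliably triggers the fracture guard.
#'
#' The default reference load is half the phantom's own resultant force at
#' the 1% compression solve, which puts the strut well over the risk
#' threshold while keeping peak strains inside the range where one tenth of
#' the load is safe.
#'
#' @param spec A [phantom_spec()]; defaults to one thin strut of low-density
#'   callus in a widened gap.
#' @param reference_load Reference applied force (N); `NULL` (default) uses
#'   `0.5 * F_resultant` of the verification solve.
#' @param model,bc Material model and boundary conditions for the
#'   verification solve.
#' @return A list: `volume`, `masks`, `spec`, `reference_load` (N),
#'   `over_count` (bone voxels >= 10,000 microstrain at the reference load),
#'   `solution` (the verification `fe_solution`), and `material` (the
#'   `material_volume` used).
#' @export
make_overloaded_strut_phantom <- function(spec = NULL, reference_load = NULL,
                                          model = material_model(),
                                          bc = bc_spec()) {
  if (is.null(spec)) {
    spec <- phantom_spec(gap_width = 10L, strut_count = 1L, strut_radius = 2.2,
                         bridge_fraction = 0, callus_density = 420, seed = 7L)
  }
  ph <- make_osteotomy_phantom(spec)
  mv <- build_material_volume(ph$volume, model)
  sol <- solve_microfe(mv, bc)
  if (is.null(reference_load)) reference_load <- 0.5 * sol$f_resultant
  mask <- bone_mask(mv)
  scaled <- sol$eff_strain * (reference_load / sol$f_resultant)
  over <- sum(scaled[mask] >= 10000)
  if (over <= 50) {
    stop("phantom failed its over-threshold contract (", over,
         " voxels >= 10,000 microstrain at the reference load); ",
         "adjust the spec", call. = FALSE)
  }
  c(ph, list(reference_load = reference_load, over_count = over,
             solution = sol, material = mv))
}

#' Deterministic heterogeneous cohort of healing series
#'
#' A reproducible synthetic cohort for constant-vs-adaptive loading studies:
#' formation-like animals (loaded-group analogue) and resorption-like animals
#' (control-group analogue), with per-animal anatomy (cortex radius and wall
#' thickness, gap width, bridging state, callus density, strut pattern) drawn
#' from seeded jitter around the phantom defaults.
#'
#' @param seed Integer seed controlling every per-animal parameter.
#' @param n_formation,n_resorption Number of animals per mode.
#' @param shape Grid shape shared by the cohort.
#' @param n_time Number of weekly time points per animal.
#' @return A tibble with one row per animal: `animal`, `group` (`"loaded"`
#'   for formation-like, `"control"` for resorption-like), `mode`, and a
#'   `series_spec` list-column of [healing_series_spec()] objects.
#' @export
example_cohort <- function(seed = 1L, n_formation = 3L, n_resorption = 2L,
                           shape = c(48L, 48L, 60L), n_time = 5L) {
  n <- n_formation + n_resorption
  if (n < 1L) stop("cohort needs at least one animal", call. = FALSE)
  modes <- rep(c("formation", "resorption"), c(n_formation, n_resorption))
  specs <- with_phantom_rng(seed, {
    lapply(seq_len(n), function(i) {
      base <- phantom_spec(
        shape = shape,
        cortex_radius = stats::runif(1, 12.5, 15.5),
        cortex_thickness = stats::runif(1, 3.5, 5.5),
        gap_width = sample(7:10, 1),
        callus_density = stats::runif(1, 440, 560),
        strut_count = sample(2:4, 1),
        strut_radius = stats::runif(1, 1.6, 2.4),
        bridge_fraction = if (modes[i] == "formation") {
          stats::runif(1, 0.2, 0.4)
        } else {
          stats::runif(1, 0.55, 0.75)
        },
        collar_radius = if (modes[i] == "formation") stats::runif(1, 0, 1) else 0,
        seed = seed * 1000L + i
      )
      healing_series_spec(base, n_time = n_time, mode = modes[i])
    })
  })
  tibble::tibble(
    animal = sprintf("A%02d", seq_len(n)),
    group = ifelse(modes == "formation", "loaded", "control"),
    mode = modes,
    series_spec = specs
  )
}
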