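#' 3-D mineral density volume
#'
#' The basic image container of the pipeline: a 3-D array of volumetric bone
#' mineral density (mg HA/cm^3) on an isotropic voxel grid. The third array
#' axis is the axial (loading) direction; shapes are reported as (x, y, z).
#' Indexing follows R's 1-based convention.
#'
#' @param values 3-D numeric array of densities (mg HA/cm^3).
#' @param voxel_size Isotropic voxel edge length in mm (default 0.0105, i.e.
#'   10.5 micrometre micro-CT resolution).
#' @param metadata Free-form provenance list (scan settings, time point label,
#'   registration flag, ...).
#' @param clamp Clamp negative densities to zero (default `TRUE`).
#' @return A `density_volume` object: a list with elements `values`,
#'   `voxel_size` and `metadata`.
#' @examples
#' vol <- density_volume(array(500, c(4, 4, 4)))
#' dim(vol)
#' @export
density_volume <- function(values, voxel_size = 0.0105, metadata = list(),
                           clamp = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (mm)", call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("densities must be finite", call. = FALSE)
  }
  if (dim(values)[3L] < 2L) {
    stop("volume needs at least 2 axial slices", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (clamp) values[values < 0] <- 0
  if (any(values < 0)) stop("densities must be >= 0", call. = FALSE)
  structure(
    list(values = values, voxel_size = voxel_size, metadata = metadata),
    class = "density_volume"
  )
}

#' @export
dim.density_volume <- function(x) dim(x$values)

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<density_volume> %d x %d x %d voxels @ %.4g mm (%.3g mm axial length)\n",
    d[1], d[2], d[3], x$voxel_size, d[3] * x$voxel_size
  ))
  cat(sprintf("  density range: %.1f - %.1f mg HA/cm^3\n",
              min(x$values), max(x$values)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname density_volume
#' @param x Object to test.
#' @export
is_density_volume <- function(x) inherits(x, "density_volume")

assert_volume <- function(vol) {
  if (!is_density_volume(vol)) {
    stop("expected a `density_volume` object", call. = FALSE)
  }
  invisible(vol)
}

#' Crop a volume to a rectangular region
#'
#' Mirrors the acquisition-side cropping step in which raw scans are reduced
#' to a fixed region of interest (e.g. 300 x 300 x 210 voxels between the
#' fixation screws). The crop is recorded in the metadata.
#'
#' @param vol A [density_volume()].
#' @param origin Integer vector (x, y, z), 1-based index of the region's first
#'   voxel.
#' @param shape Integer vector (x, y, z), the size of the region.
#' @return A `density_volume` of exactly the requested shape.
#' @examples
#' vol <- density_volume(array(runif(8000, 0, 100), c(20, 20, 20)))
#' dim(crop_to_region(vol, c(1, 1, 1), c(10, 10, 10)))
#' @export
crop_to_region <- function(vol, origin, shape) {
  assert_volume(vol)
  origin <- as.integer(origin); shape <- as.integer(shape)
  if (length(origin) != 3L || length(shape) != 3L) {
    stop("`origin` and `shape` must each have 3 components", call. = FALSE)
  }
  if (any(shape < 1L)) stop("crop shape must be positive", call. = FALSE)
  d <- dim(vol)
  if (any(origin < 1L) || any(origin + shape - 1L > d)) {
    stop("crop region exceeds volume bounds", call. = FALSE)
  }
  idx <- Map(function(o, s) seq.int(o, o + s - 1L), origin, shape)
  out <- vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  md <- vol$metadata
  md$crop <- list(origin = origin, shape = shape)
  density_volume(out, vol$voxel_size, md)
}

#' Trim axial slices from both ends of a volume
#'
#' After longitudinal registration, rotation/translation leaves partially
#' empty end slices; these are removed (e.g. 210 slices trimmed by 15 + 15 to
#' 180). Transverse shape is unchanged.
#'
#' @param vol A [density_volume()].
#' @param n_top,n_bottom Number of axial slices to remove from the top (last
#'   slices) and bottom (first slices).
#' @return The trimmed `density_volume`.
#' @export
trim_axial <- function(vol, n_top = 15L, n_bottom = 15L) {
  assert_volume(vol)
  n_top <- as.integer(n_top); n_bottom <- as.integer(n_bottom)
  if (n_top < 0L || n_bottom < 0L) stop("trim counts must be >= 0", call. = FALSE)
  nz <- dim(vol)[3L]
  if (n_top + n_bottom >= nz - 1L) {
    stop("trim would consume the whole volume (need >= 2 slices left)",
         call. = FALSE)
  }
  keep <- seq.int(n_bottom + 1L, nz - n_top)
  md <- vol$metadata
  md$trim <- c(top = n_top, bottom = n_bottom)
  density_volume(vol$values[, , keep, drop = FALSE], vol$voxel_size, md)
}

#' Gaussian filter specification
#'
#' Parameters of the image smoothing applied before material mapping:
#' `sigma` is the Gaussian standard deviation in voxels and `support` the
#' integer half-width at which the kernel is truncated, so the kernel spans
#' `2 * support + 1` voxels per axis and is renormalized to unit sum. The
#' defaults (sigma 1.2, support 1, a 3x3x3 kernel) are the standard micro-CT
#' preprocessing choice for this pipeline family.
#'
#' @param sigma Gaussian standard deviation in voxel units (> 0).
#' @param support Integer kernel half-width in voxels (>= 1).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(sigma = 1.2, support = 1L) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  support <- as.integer(support)
  if (is.na(support) || support < 1L) stop("`support` must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, support = support), class = "filter_spec")
}

gaussian_kernel_1d <- function(spec) {
  k <- stats::dnorm(seq.int(-spec$support, spec$support), sd = spec$sigma)
  k / sum(k)
}

# 1-D convolution along one axis of a 3-D array with mirror (reflect) padding.
convolve_axis <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  n <- dim(a)[axis]
  # mirror indices: for offset d, index i+d reflected into 1..n
  out <- array(0, dim(a))
  for (t in seq_along(kernel)) {
    d <- t - 1L - half
    idx <- seq_len(n) + d
    idx[idx < 1L] <- 2L - idx[idx < 1L]          # reflect about first sample
    idx[idx > n] <- 2L * n - idx[idx > n]        # reflect about last sample
    shifted <- switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE]
    )
    out <- out + kernel[t] * shifted
  }
  out
}

#' Smooth a density volume with a truncated Gaussian kernel
#'
#' Separable 3-D convolution with the unit-sum kernel described by
#' [filter_spec()]. Boundaries use mirror (reflect) padding so faces are not
#' artificially darkened. Output shape equals input shape; constant volumes
#' are preserved exactly (up to round-off).
#'
#' @param vol A [density_volume()].
#' @param spec A [filter_spec()]; default sigma 1.2, support 1.
#' @return The filtered `density_volume`.
#' @export
gaussian_filter <- function(vol, spec = filter_spec()) {
  assert_volume(vol)
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, as.list(spec))
  k <- gaussian_kernel_1d(spec)
  v <- vol$values
  for (axis in 1:3) v <- convolve_axis(v, k, axis)
  md <- vol$metadata
  md$filter <- c(sigma = spec$sigma, support = spec$support)
  density_volume(v, vol$voxel_size, md)
}

#' Preprocess a registered density volume
#'
#' Convenience chain of the standard preprocessing: optional crop, axial trim
#' of registration-damaged end slices, and Gaussian smoothing.
#'
#' @param vol A [density_volume()] (pre-registered across time points).
#' @param trim Length-2 integer vector `c(top, bottom)` of axial slices to
#'   remove; `c(0, 0)` disables trimming.
#' @param filter A [filter_spec()] or `NULL` to skip smoothing.
#' @return The preprocessed `density_volume`.
#' @export
preprocess_volume <- function(vol, trim = c(0L, 0L), filter = filter_spec()) {
  assert_volume(vol)
  if (any(trim > 0L)) vol <- trim_axial(vol, trim[1], trim[2])
  if (!is.null(filter)) vol <- gaussian_filter(vol, filter)
  vol
}
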