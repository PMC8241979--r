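#' Median effective strain
#'
#' Sample median (mean of the middle two values for even sizes) of a strain
#' distribution — the per-animal summary used throughout cohort reporting.
#'
#' @param dist A [strain_distribution()] or numeric vector (microstrain).
#' @return Median strain in microstrain.
#' @export
median_strain <- function(dist) {
  if (inherits(dist, "strain_distribution")) dist <- dist$values
  dist <- as.numeric(dist)
  if (length(dist) == 0L) stop("empty strain distribution", call. = FALSE)
  stats::median(dist)
}

#' Fixed-grid histogram specification
#'
#' The reporting histogram: 250 left-closed right-open bins over
#' 0-15,000 microstrain (bin width 60), with values at or above the upper
#' range collected in an explicit overflow bucket so counts are conserved.
#'
#' @param low,high Range (microstrain).
#' @param bins Number of bins (>= 1).
#' @return A `histogram_spec` object with the implied `width`.
#' @export
histogram_spec <- function(low = 0, high = 15000, bins = 250L) {
  bins <- as.integer(bins)
  if (!(high > low) || bins < 1L) {
    stop("need high > low and bins >= 1", call. = FALSE)
  }
  structure(list(low = low, high = high, bins = bins,
                 width = (high - low) / bins),
            class = "histogram_spec")
}

#' Histogram of a strain distribution
#'
#' @param dist A [strain_distribution()] or numeric vector (microstrain).
#' @param spec A [histogram_spec()].
#' @return A tibble with one row per bin plus a final overflow row
#'   (`overflow = TRUE`, `upper = Inf`): columns `bin`, `lower`, `upper`,
#'   `count`, `overflow`. Counts always sum to the sample size.
#' @export
strain_histogram <- function(dist, spec = histogram_spec()) {
  if (inherits(dist, "strain_distribution")) dist <- dist$values
  dist <- as.numeric(dist)
  if (!inherits(spec, "histogram_spec")) {
    stop("expected a `histogram_spec`", call. = FALSE)
  }
  edges <- seq(spec$low, spec$high, length.out = spec$bins + 1L)
  in_range <- dist >= spec$low & dist < spec$high
  idx <- pmin(floor((dist[in_range] - spec$low) / spec$width), spec$bins - 1L)
  counts <- tabulate(idx + 1L, nbins = spec$bins)
  overflow <- sum(dist >= spec$high)
  tibble::tibble(
    bin = c(seq_len(spec$bins), NA_integer_),
    lower = c(edges[-length(edges)], spec$high),
    upper = c(edges[-1L], Inf),
    count = c(counts, overflow),
    overflow = c(rep(FALSE, spec$bins), TRUE)
  )
}

#' Per-group, per-week summary of per-animal median strains
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-animal
#' medians in every (group, week) cell. Cells with a single animal report the
#' mean with `sd = NA`; the summary is invariant to animal order.
#'
#' @param records A data frame with columns `group`, `week` and
#'   `median_strain` (one row per animal per week).
#' @return A tibble with `group`, `week`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("group", "week", "median_strain")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$group, .data$week) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$median_strain),
      sd = if (dplyr::n() >= 2L) stats::sd(.data$median_strain) else NA_real_,
      .groups = "drop"
    )
}

#' Normalized bone volume of a longitudinal series
#'
#' Bone voxel count times voxel volume per time point, divided by the week 0
#' value (BV/BV0).
#'
#' @param masks List of logical bone masks, ordered by time point (week 0
#'   first).
#' @param voxel_size Voxel edge (mm).
#' @return A tibble with `week`, `bv` (mm^3) and `bv_ratio`.
#' @export
normalized_bone_volume <- function(masks, voxel_size = 0.0105) {
  if (length(masks) == 0L) stop("no masks supplied", call. = FALSE)
  bv <- vapply(masks, function(m) sum(m) * voxel_size^3, 0)
  if (bv[1] <= 0) stop("week 0 bone mask is empty", call. = FALSE)
  tibble::tibble(week = seq_along(bv) - 1L, bv = bv, bv_ratio = bv / bv[1])
}

#' One-row summary of an adaptive-loading session
#'
#' @param x An `rtfe_session`.
#' @param ... Unused.
#' @return A tibble with the simulation resultant force, the pre-matching
#'   median strain, the matched and final (post-guard) forces, the KS
#'   statistic, guard outcome and bone voxel count.
#' @export
glance.rtfe_session <- function(x, ...) {
  tibble::tibble(
    f_resultant = x$dist_sim$f_resultant,
    median_sim = median_strain(x$dist_sim),
    n_bone = length(x$dist_sim$values),
    f_matched = x$plan$f_matched,
    ks = x$plan$ks,
    converged = x$plan$converged,
    f_final = x$plan$f_final,
    guard_ok = x$plan$guard_ok,
    guard_steps = nrow(x$plan$guard_trace) - 1L,
    median_final = if (!is.null(x$dist_final)) {
      median_strain(x$dist_final)
    } else NA_real_
  )
}

#' Compare constant and adaptive loading on a cohort
#'
#' Both scenarios are evaluated on the identical solves: the constant
#' scenario rescales each animal-week strain distribution to a fixed applied
#' force, while the adaptive scenario uses the session's final (post-guard)
#' recommended force. Reports the per-(group, week) mean +/- SD of median
#' strains under each scenario, the adaptive-to-constant SD ratio, and the
#' per-animal recommended-load trajectories.
#'
#' @param records A data frame with one row per animal per week, columns
#'   `animal`, `group`, `week`, `f_resultant`, `median_sim` (median strain at
#'   the simulation force, microstrain) and `f_final` (post-guard recommended
#'   force, N) — e.g. [glance.rtfe_session()] rows plus identifiers.
#' @param constant_force The fixed applied force of the constant scenario (N),
#'   default 10.
#' @return A `scenario_comparison` object: tibbles `summary` (group, week,
#'   scenario, n, mean, sd), `sd_ratio` and `loads`.
#' @export
compare_scenarios <- function(records, constant_force = 10) {
  records <- tibble::as_tibble(records)
  need <- c("animal", "group", "week", "f_resultant", "median_sim", "f_final")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # every animal must carry the same week set, once each
  weeks <- records |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(w = paste(sort(.data$week), collapse = ","),
                     dup = anyDuplicated(.data$week) > 0L)
  if (any(weeks$dup) || length(unique(weeks$w)) != 1L) {
    stop("scenario alignment error: animals differ in their week coverage",
         call. = FALSE)
  }
  long <- records |>
    dplyr::mutate(
      constant = .data$median_sim * constant_force / .data$f_resultant,
      adaptive = .data$median_sim * .data$f_final / .data$f_resultant
    ) |>
    tidyr::pivot_longer(c("constant", "adaptive"), names_to = "scenario",
                        values_to = "median_strain")
  summary <- long |>
    dplyr::group_by(.data$group, .data$week, .data$scenario) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$median_strain),
      sd = if (dplyr::n() >= 2L) stats::sd(.data$median_strain) else NA_real_,
      .groups = "drop"
    )
  sd_ratio <- summary |>
    dplyr::select("group", "week", "scenario", "sd") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "sd") |>
    dplyr::mutate(sd_ratio = ifelse(.data$constant > 0,
                                    .data$adaptive / .data$constant, NA_real_))
  loads <- records |>
    dplyr::select("animal", "group", "week", "f_final") |>
    dplyr::arrange(.data$animal, .data$week)
  structure(list(summary = summary, sd_ratio = sd_ratio, loads = loads,
                 constant_force = constant_force),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> constant %g N vs adaptive loading\n",
              x$constant_force))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Group-vs-group Kolmogorov-Smirnov comparison
#'
#' KS statistic between the pooled strain distributions of two groups of
#' samples, per week — the descriptive cross-group comparison of the
#' reporting layer (reuses [ks_statistic()]).
#'
#' @param a,b Numeric vectors (pooled strains, microstrain).
#' @return The KS statistic D.
#' @export
group_ks <- function(a, b) ks_statistic(a, b)
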