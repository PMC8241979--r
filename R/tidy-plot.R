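#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a strain distribution into a tibble
#'
#' @param x A [strain_distribution()].
#' @param ... Unused.
#' @return A tibble with one row per bone voxel: `strain` (microstrain) and
#'   the forces the values are expressed at.
#' @export
tidy.strain_distribution <- function(x, ...) {
  tibble::tibble(strain = x$values, f_applied = x$f_applied,
                 f_resultant = x$f_resultant)
}

#' @rdname tidy.strain_distribution
#' @export
glance.strain_distribution <- function(x, ...) {
  tibble::tibble(n = length(x$values), median = stats::median(x$values),
                 q25 = unname(stats::quantile(x$values, 0.25)),
                 q75 = unname(stats::quantile(x$values, 0.75)),
                 f_applied = x$f_applied, f_resultant = x$f_resultant)
}

#' Tidy a load plan
#'
#' `tidy()` returns the fracture-guard trace (one row per trial force);
#' `glance()` a one-row summary of the matched and final loads.
#'
#' @param x A `load_plan`.
#' @param ... Unused.
#' @export
tidy.load_plan <- function(x, ...) {
  if (is.null(x$guard_trace)) {
    return(tibble::tibble(step = integer(), force = double(),
                          count = integer()))
  }
  x$guard_trace
}

#' @rdname tidy.load_plan
#' @export
glance.load_plan <- function(x, ...) {
  tibble::tibble(
    f_matched = x$f_matched, ks = x$ks, converged = x$converged,
    evaluations = x$evaluations, f_final = x$f_final,
    guard_ok = x$guard_ok,
    guard_steps = if (is.null(x$guard_trace)) NA_integer_
                  else nrow(x$guard_trace) - 1L
  )
}

#' Tidy an adaptive-loading session
#'
#' One row per bone voxel of the pre-matching (simulation-force) and, when
#' the guard succeeded, post-guard distributions.
#'
#' @param x An `rtfe_session`.
#' @param ... Unused.
#' @export
tidy.rtfe_session <- function(x, ...) {
  out <- dplyr::mutate(tidy(x$dist_sim), stage = "simulation")
  if (!is.null(x$dist_final)) {
    out <- dplyr::bind_rows(out,
                            dplyr::mutate(tidy(x$dist_final), stage = "final"))
  }
  out
}

#' Plot a strain distribution as its reporting histogram
#'
#' @param object A [strain_distribution()].
#' @param spec A [histogram_spec()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_distribution <- function(object, spec = histogram_spec(), ...) {
  h <- strain_histogram(object, spec)
  h <- h[!h$overflow, ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$lower + spec$width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = spec$width, fill = "steelblue") +
    ggplot2::labs(x = "effective strain (microstrain)", y = "bone voxels",
                  title = sprintf("Mechanical environment at %.2f N",
                                  object$f_applied)) +
    ggplot2::theme_minimal()
}

#' Plot the fracture-guard trace of a load plan
#'
#' Trial force against over-threshold voxel count, with the voxel limit drawn
#' as a horizontal reference.
#'
#' @param object A `load_plan` that has been through [fracture_guard()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.load_plan <- function(object, ...) {
  if (is.null(object$guard_trace)) {
    stop("plan has no guard trace; run fracture_guard() first", call. = FALSE)
  }
  limit <- object$guard$voxel_limit %||% 50
  ggplot2::ggplot(object$guard_trace,
                  ggplot2::aes(x = .data$force, y = .data$count)) +
    ggplot2::geom_hline(yintercept = limit, linetype = 2, colour = "firebrick") +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "applied force (N)",
                  y = "voxels at/above strain threshold",
                  title = "Fracture-guard load downscaling") +
    ggplot2::theme_minimal()
}

#' Plot a constant-vs-adaptive scenario comparison
#'
#' Mean +/- SD of per-animal median strains per week, one panel per group,
#' coloured by scenario.
#'
#' @param object A `scenario_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$week, y = .data$mean,
                               colour = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$scenario),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "week", y = "median effective strain (microstrain)",
                  title = "Median strain under constant vs adaptive loading") +
    ggplot2::theme_minimal()
}
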