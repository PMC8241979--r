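#' Effective-strain distribution at a stated applied force
#'
#' The "mechanical environment": the multiset of effective strains over the
#' bone voxels, together with the simulation resultant force `f_resultant`
#' and the applied force `f_applied` the values are expressed at. Because the
#' model is linear, the same solve serves any applied force via
#' [scale_strains()].
#'
#' @param values Numeric vector of effective strains (microstrain), all >= 0.
#' @param f_resultant Resultant force of the originating simulation (N).
#' @param f_applied Applied force the values are currently expressed at (N);
#'   defaults to `f_resultant`.
#' @param provenance Free-form provenance list (volume id, time point, ...).
#' @return A `strain_distribution` object.
#' @export
strain_distribution <- function(values, f_resultant, f_applied = f_resultant,
                                provenance = list()) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("strain distribution is empty", call. = FALSE)
  if (anyNA(values) || any(values < 0)) {
    stop("strains must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(f_resultant) || f_resultant <= 0) {
    stop("`f_resultant` must be > 0", call. = FALSE)
  }
  if (!is.finite(f_applied) || f_applied < 0) {
    stop("`f_applied` must be >= 0", call. = FALSE)
  }
  structure(list(values = values, f_resultant = f_resultant,
                 f_applied = f_applied, provenance = provenance),
            class = "strain_distribution")
}

#' @export
print.strain_distribution <- function(x, ...) {
  cat(sprintf(
    "<strain_distribution> %d bone voxels @ F_applied = %.3g N (F_resultant = %.3g N)\n",
    length(x$values), x$f_applied, x$f_resultant))
  cat(sprintf("  median %.0f microstrain, IQR [%.0f, %.0f]\n",
              stats::median(x$values),
              stats::quantile(x$values, 0.25), stats::quantile(x$values, 0.75)))
  invisible(x)
}

#' @export
length.strain_distribution <- function(x) length(x$values)

#' Rescale a strain distribution to an applied force
#'
#' Linear elasticity makes strain proportional to load, so strains under any
#' applied force are the simulated strains multiplied by
#' `F_applied / F_resultant`.
#'
#' @param dist A [strain_distribution()] (values at its simulation force).
#' @param f_applied Applied force (N), >= 0.
#' @return The rescaled `strain_distribution` with `f_applied` recorded.
#' @examples
#' d <- strain_distribution(c(100, 200, 300), f_resultant = 10)
#' scale_strains(d, 20)$values
#' @export
scale_strains <- function(dist, f_applied) {
  if (!inherits(dist, "strain_distribution")) {
    stop("expected a `strain_distribution`", call. = FALSE)
  }
  if (!is.finite(f_applied) || f_applied < 0) {
    stop("`f_applied` must be >= 0", call. = FALSE)
  }
  # values are stored at dist$f_applied; re-express at the new force
  ratio <- f_applied / dist$f_applied
  strain_distribution(dist$values * ratio, dist$f_resultant, f_applied,
                      dist$provenance)
}

#' Build a reference target distribution
#'
#' Rescales a reference strain sample (ideally from a subject with good
#' healing progression) so its median equals the target (700 microstrain by
#' default). The target acts as the idealized mechanical environment that
#' adaptive loading tries to reproduce.
#'
#' @param sample Numeric strain sample (microstrain) with strictly positive
#'   median.
#' @param target_median Desired median (microstrain), default 700.
#' @return A `target_distribution` object with `values` and `target_median`.
#' @export
make_target <- function(sample, target_median = 700) {
  if (inherits(sample, "strain_distribution")) sample <- sample$values
  if (inherits(sample, "target_distribution")) sample <- sample$values
  sample <- as.numeric(sample)
  if (length(sample) == 0L) stop("target sample is empty", call. = FALSE)
  med <- stats::median(sample)
  if (!is.finite(med) || med <= 0) {
    stop("target sample must have a strictly positive median", call. = FALSE)
  }
  structure(list(values = sample * target_median / med,
                 target_median = target_median),
            class = "target_distribution")
}

#' @export
print.target_distribution <- function(x, ...) {
  cat(sprintf("<target_distribution> %d values, median %.0f microstrain\n",
              length(x$values), stats::median(x$values)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum of the absolute difference between the empirical CDFs of two
#' samples. Computed directly (ties allowed) rather than through a test
#' object, since only the statistic is needed for distribution matching.
#'
#' @param a,b Non-empty numeric samples.
#' @return The KS statistic D in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2), c(1, 3))  # 0.5
#' @export
ks_statistic <- function(a, b) {
  if (inherits(a, "strain_distribution") || inherits(a, "target_distribution"))
    a <- a$values
  if (inherits(b, "strain_distribution") || inherits(b, "target_distribution"))
    b <- b$values
  if (length(a) == 0L || length(b) == 0L) {
    stop("KS statistic needs two non-empty samples", call. = FALSE)
  }
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  max(abs(Fa - Fb))
}

# KS statistic between the distribution rescaled to force F and the target.
ks_at_force <- function(dist, target, f) {
  ks_statistic(dist$values * (f / dist$f_applied), target$values)
}

#' Match the applied load to a target distribution
#'
#' One-dimensional Nelder-Mead over the applied force, minimizing the
#' two-sample KS statistic between the force-rescaled strain distribution and
#' the target. The search starts from the median-matching force
#' `F0 = F_applied * median(target) / median(dist)` with initial simplex
#' `{F0, 1.05 F0}`. Because D is piecewise constant in the scale factor for
#' finite samples, convergence is declared on simplex size (0.01 N on force)
#' and spread of D (1e-4), not on gradients.
#'
#' @param dist A [strain_distribution()].
#' @param target A `target_distribution` from [make_target()].
#' @param f_tol Absolute force tolerance (N).
#' @param d_tol Absolute tolerance on the KS spread.
#' @param max_eval Evaluation cap; exceeding it flags (not fails) the plan.
#' @param load_grid Optional actuator grid (N); when given the matched force
#'   is snapped to the grid member with the lowest D before return.
#' @return A `load_plan` with the matched force `f_matched`, its KS statistic
#'   `ks`, the optimizer trace, and a convergence flag. The fracture-guard
#'   fields are filled by [fracture_guard()].
#' @export
match_load <- function(dist, target, f_tol = 0.01, d_tol = 1e-4,
                       max_eval = 200, load_grid = NULL) {
  if (!inherits(dist, "strain_distribution")) {
    stop("expected a `strain_distribution`", call. = FALSE)
  }
  if (!inherits(target, "target_distribution")) {
    stop("expected a `target_distribution`", call. = FALSE)
  }
  med <- stats::median(dist$values)
  if (med <= 0) stop("distribution median must be > 0 to match", call. = FALSE)
  f0 <- dist$f_applied * stats::median(target$values) / med

  evals <- 0L
  trace <- vector("list", 0L)
  fn <- function(f) {
    if (f <= 0) return(1 + abs(f))  # penalize non-physical forces
    d <- ks_at_force(dist, target, f)
    evals <<- evals + 1L
    trace[[length(trace) + 1L]] <<- c(force = f, ks = d)
    d
  }

  # 1-D Nelder-Mead: simplex of two points, reflect/expand/contract/shrink
  x <- c(f0, 1.05 * f0)
  fx <- vapply(x, fn, 0)
  converged <- FALSE
  while (evals < max_eval) {
    o <- order(fx)
    x <- x[o]; fx <- fx[o]
    if (abs(x[2] - x[1]) <= f_tol && abs(fx[2] - fx[1]) <= d_tol) {
      converged <- TRUE
      break
    }
    xr <- x[1] + (x[1] - x[2])       # reflection of the worst point
    fr <- fn(xr)
    if (fr < fx[1]) {
      xe <- x[1] + 2 * (x[1] - x[2]) # expansion
      fe <- fn(xe)
      if (fe < fr) { x[2] <- xe; fx[2] <- fe } else { x[2] <- xr; fx[2] <- fr }
    } else if (fr < fx[2]) {
      x[2] <- xr; fx[2] <- fr
    } else {
      # contraction toward the best point (doubles as the 1-D shrink)
      xc <- x[1] + 0.5 * (x[2] - x[1])
      fc <- fn(xc)
      x[2] <- xc; fx[2] <- fc
    }
  }
  o <- order(fx)
  f_star <- x[o[1]]; d_star <- fx[o[1]]

  if (!is.null(load_grid)) {
    if (length(load_grid) == 0L || any(load_grid <= 0)) {
      stop("`load_grid` must be a non-empty vector of positive forces",
           call. = FALSE)
    }
    dg <- vapply(load_grid, function(f) ks_at_force(dist, target, f), 0)
    pick <- order(dg, load_grid)[1L]
    f_star <- load_grid[pick]; d_star <- dg[pick]
  }

  trace_tbl <- tibble::tibble(
    eval = seq_along(trace),
    force = vapply(trace, `[[`, 0, "force"),
    ks = vapply(trace, `[[`, 0, "ks")
  )
  new_load_plan(f_matched = f_star, ks = d_star, converged = converged,
                evaluations = evals, trace = trace_tbl, f0 = f0)
}

new_load_plan <- function(f_matched, ks, converged, evaluations, trace, f0,
                          f_final = f_matched, guard_trace = NULL,
                          guard_ok = NA, guard = NULL) {
  structure(
    list(f_matched = f_matched, ks = ks, converged = converged,
         evaluations = evaluations, trace = trace, f0 = f0,
         f_final = f_final, guard_trace = guard_trace, guard_ok = guard_ok,
         guard = guard),
    class = "load_plan"
  )
}

#' @export
print.load_plan <- function(x, ...) {
  cat(sprintf("<load_plan> matched force %.3f N (KS D = %.4f, %s, %d evals)\n",
              x$f_matched, x$ks,
              if (x$converged) "converged" else "NOT converged",
              x$evaluations))
  if (!is.null(x$guard_trace)) {
    cat(sprintf("  fracture guard: final force %.3f N after %d step(s), %s\n",
                x$f_final, nrow(x$guard_trace) - 1L,
                if (isTRUE(x$guard_ok)) "ok" else "FAILED (do not load)"))
  }
  invisible(x)
}

#' Rank a discrete menu of candidate loads
#'
#' The plot-and-select alternative to automatic matching: every actuator-
#' feasible load is scored by its KS distance to the target and returned as a
#' table sorted by D (ties broken by the smaller force), together with summary
#' statistics of each rescaled distribution.
#'
#' @param dist A [strain_distribution()].
#' @param target A `target_distribution`.
#' @param loads Numeric vector of candidate forces (N), all > 0.
#' @return A tibble with columns `rank`, `force`, `ks`, `median`, `q25`,
#'   `q75`, sorted ascending by `ks`.
#' @export
enumerate_loads <- function(dist, target, loads) {
  if (!inherits(dist, "strain_distribution")) {
    stop("expected a `strain_distribution`", call. = FALSE)
  }
  if (length(loads) == 0L || any(!is.finite(loads)) || any(loads <= 0)) {
    stop("`loads` must be a non-empty vector of positive forces", call. = FALSE)
  }
  rows <- purrr::map(loads, function(f) {
    v <- dist$values * (f / dist$f_applied)
    tibble::tibble(force = f, ks = ks_statistic(v, target$values),
                   median = stats::median(v),
                   q25 = unname(stats::quantile(v, 0.25)),
                   q75 = unname(stats::quantile(v, 0.75)))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$ks, .data$force)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1L)
}

#' Fracture-guard parameters
#'
#' Defaults follow the conservative refracture screen: count bone voxels at or
#' above 10,000 microstrain (1% strain); while the count is at or above 50
#' voxels, downscale the load by 2 N and recount.
#'
#' @param threshold Strain threshold (microstrain), comparison is `>=`.
#' @param voxel_limit Maximum tolerated over-threshold voxel count; the loop
#'   stops when the count is strictly below this.
#' @param decrement Actuator force step (N).
#' @return A `guard_params` object.
#' @export
guard_params <- function(threshold = 10000, voxel_limit = 50, decrement = 2) {
  stopifnot(threshold > 0, voxel_limit >= 1, decrement > 0)
  structure(list(threshold = threshold, voxel_limit = voxel_limit,
                 decrement = decrement),
            class = "guard_params")
}

#' Screen a matched load against refracture risk
#'
#' Strain matching can leave thin callus struts dangerously strained, so the
#' matched load is screened: the number of bone voxels at or above the strain
#' threshold is counted at the current force; while the count reaches the
#' voxel limit, the force is reduced by the actuator decrement and the count
#' recomputed (by exact linear rescaling — no re-solve is needed for a linear
#' model). Every trial is recorded. If the force would drop to zero or below
#' before the criterion is met, the plan is flagged as a guard failure ("do
#' not load"), never silently clamped.
#'
#' @param dist A [strain_distribution()] (the same solve the plan was matched
#'   on).
#' @param plan A `load_plan` from [match_load()].
#' @param params A [guard_params()].
#' @return The completed `load_plan`: `f_final`, `guard_ok`, and a
#'   `guard_trace` tibble with one row per trial (`force`, `count`,
#'   `largest_component` when a field is supplied).
#' @export
fracture_guard <- function(dist, plan, params = guard_params()) {
  if (!inherits(plan, "load_plan")) stop("expected a `load_plan`", call. = FALSE)
  if (!inherits(dist, "strain_distribution")) {
    stop("expected a `strain_distribution`", call. = FALSE)
  }
  count_at <- function(f) {
    sum(dist$values * (f / dist$f_applied) >= params$threshold)
  }
  f <- plan$f_matched
  trace <- list()
  guard_ok <- TRUE
  repeat {
    n_over <- count_at(f)
    trace[[length(trace) + 1L]] <- c(force = f, count = n_over)
    if (n_over < params$voxel_limit) break
    if (f - params$decrement <= 0) {
      guard_ok <- FALSE
      break
    }
    f <- f - params$decrement
  }
  plan$f_final <- if (guard_ok) f else NA_real_
  plan$guard_ok <- guard_ok
  plan$guard_trace <- tibble::tibble(
    step = seq_along(trace) - 1L,
    force = vapply(trace, `[[`, 0, "force"),
    count = vapply(trace, function(x) as.integer(x[["count"]]), 0L)
  )
  plan$guard <- params
  plan
}

#' Largest connected cluster of over-threshold voxels
#'
#' Highly strained voxels that lie next to one another in thin callus struts
#' are the actual refracture concern, so the size of the largest 26-connected
#' over-threshold component is reported alongside the raw count. It is
#' informational: the guard's stopping rule uses the count only.
#'
#' @param solution An `fe_solution`.
#' @param mask Bone mask (logical array on the element grid).
#' @param f_applied Applied force (N) at which to threshold.
#' @param threshold Strain threshold (microstrain).
#' @return Integer: size of the largest 26-connected component (0 if none).
#' @export
overstrain_cluster_size <- function(solution, mask, f_applied,
                                    threshold = 10000) {
  scaled <- solution$eff_strain * (f_applied / solution$f_resultant)
  over <- scaled >= threshold & mask
  if (!any(over)) return(0L)
  max(connected_component_sizes(over))
}

# 26-connected component sizes of a logical 3-D array (two-pass union-find on
# the voxel list; fine at the sparse occupancies seen here).
connected_component_sizes <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(integer(0))
  d <- dim(mask)
  coords <- arrayInd(idx, d)
  key <- (coords[, 3] - 1) * (d[1] * d[2]) + (coords[, 2] - 1) * d[1] + coords[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (t in seq_along(key)) assign(as.character(key[t]), t, envir = lookup)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  for (t in seq_along(idx)) {
    for (r in seq_len(nrow(offsets))) {
      nb <- coords[t, ] + offsets[r, ]
      if (any(nb < 1L) || any(nb > d)) next
      nkey <- (nb[3] - 1) * (d[1] * d[2]) + (nb[2] - 1) * d[1] + nb[1]
      s <- get0(as.character(nkey), envir = lookup)
      if (!is.null(s)) {
        ra <- find(t); rb <- find(s)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  as.integer(table(roots))
}

#' Run one full adaptive-loading session
#'
#' The end-to-end chain executed while the animal is still under anaesthesia:
#' preprocess the registered density volume, build the material model, solve
#' the micro-FE problem, extract the bone strain distribution, match the
#' applied load to the target, and screen it with the fracture guard.
#'
#' @param vol A [density_volume()] (pre-registered).
#' @param target A `target_distribution`.
#' @param model A [material_model()].
#' @param bc A [bc_spec()].
#' @param guard A [guard_params()].
#' @param filter A [filter_spec()] or `NULL` to skip smoothing (e.g. for
#'   already-filtered input).
#' @param trim Axial trim `c(top, bottom)`; default none (phantoms need no
#'   registration repair).
#' @param provenance Provenance list forwarded to the strain distribution.
#' @return An `rtfe_session` object: the final load recommendation, the
#'   pre-matching (simulation-force) and post-guard strain distributions, the
#'   `load_plan`, and per-stage timings (seconds).
#' @export
rtfe_session <- function(vol, target, model = material_model(),
                         bc = bc_spec(), guard = guard_params(),
                         filter = NULL, trim = c(0L, 0L),
                         provenance = list()) {
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  vol <- tick("preprocess", preprocess_volume(vol, trim, filter))
  mv <- tick("material", build_material_volume(vol, model))
  sol <- tick("solve", solve_microfe(mv, bc))
  mask <- bone_mask(mv)
  dist <- effective_strain_field(sol, mask, provenance)
  plan <- tick("match", match_load(dist, target))
  plan <- tick("guard", fracture_guard(dist, plan, guard))
  post <- if (isTRUE(plan$guard_ok)) scale_strains(dist, plan$f_final) else NULL
  structure(
    list(plan = plan, dist_sim = dist, dist_final = post, mask = mask,
         solution = sol, timings = unlist(timings), provenance = provenance),
    class = "rtfe_session"
  )
}

#' @export
print.rtfe_session <- function(x, ...) {
  cat("<rtfe_session>\n")
  print(x$plan)
  if (!is.null(x$dist_final)) {
    cat(sprintf("  final median strain: %.0f microstrain at %.3f N\n",
                stats::median(x$dist_final$values), x$plan$f_final))
  }
  cat(sprintf("  timings (s): %s\n",
              paste(sprintf("%s %.2f", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}

#' Synthetic default target distribution
#'
#' The reference distribution a study would take from a well-healed subject
#' is not something a fresh installation has, so a synthetic stand-in is
#' provided: a log-normal strain sample (right-skewed, like the effective-
#' strain distributions of bridged defects) rescaled to the target median via
#' [make_target()]. Any real reference sample should be preferred when
#' available.
#'
#' @param n Sample size.
#' @param target_median Median after rescaling (microstrain).
#' @param sdlog Log-scale spread of the log-normal shape.
#' @param seed Integer seed.
#' @return A `target_distribution`.
#' @export
default_target <- function(n = 5000, target_median = 700, sdlog = 0.5,
                           seed = 1L) {
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
  make_target(stats::rlnorm(n, meanlog = log(target_median), sdlog = sdlog),
              target_median)
}
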