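#' Tidy an equilibrium solution
#'
#' @param x An `equilibrium` from [solve_equilibrium()].
#' @param ... Unused.
#' @return A one-row tibble: `x_eq`, `force_on_protein`, `residual`,
#'   `converged`.
#' @method tidy equilibrium
#' @export
tidy.equilibrium <- function(x, ...) {
  tibble::tibble(
    x_eq = x$x_eq,
    force_on_protein = x$force_on_protein,
    residual = x$residual,
    converged = x$converged
  )
}

#' Glance at an equilibrium solution
#'
#' @inheritParams tidy.equilibrium
#' @return A one-row tibble with the solution plus model context
#'   (`mode`, `k_protein`, `n_top`, `n_bottom`).
#' @method glance equilibrium
#' @export
glance.equilibrium <- function(x, ...) {
  tibble::tibble(
    mode = x$model$mode,
    k_protein = x$model$protein$k,
    n_top = x$model$n_top,
    n_bottom = x$model$n_bottom,
    x_eq = x$x_eq,
    force_on_protein = x$force_on_protein,
    residual = x$residual,
    converged = x$converged
  )
}

#' Tidy a bead calibration fit
#'
#' @param x A `bead_calibration` from [fit_bead_calibration()].
#' @param ... Unused.
#' @return A tibble with one row per regression term (`intercept`, `slope`)
#'   and columns `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy bead_calibration
#' @export
tidy.bead_calibration <- function(x, ...) {
  cf <- stats::coef(suppressWarnings(summary(x$fit)))
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' Glance at a bead calibration fit
#'
#' @inheritParams tidy.bead_calibration
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `sigma`, `n`.
#' @method glance bead_calibration
#' @export
glance.bead_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    n = x$n
  )
}

#' Tidy a trace segmentation
#'
#' @param x A `trace_segmentation` from [segment_trace()].
#' @param ... Unused.
#' @return The per-state summary tibble (`state`, `mean_pA`, `sd_pA`,
#'   `n_samples`, `occupancy`).
#' @method tidy trace_segmentation
#' @export
tidy.trace_segmentation <- function(x, ...) {
  x$states
}

#' Glance at a trace segmentation
#'
#' @inheritParams tidy.trace_segmentation
#' @return A one-row tibble: `n_states`, `n_transitions`, `n_samples`,
#'   `duration_s`, `single_state`.
#' @method glance trace_segmentation
#' @export
glance.trace_segmentation <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$states),
    n_transitions = x$n_transitions,
    n_samples = nrow(x$data),
    duration_s = sum(x$dwells$duration_s),
    single_state = x$single_state
  )
}

#' Tidy an ensemble summary
#'
#' @param x An `ensemble_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `mean`, `sd`, `q05`, `q50`, `q95`, `source`, `n`.
#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, sd = x$sd,
    q05 = x$quantiles[[1]], q50 = x$quantiles[[2]], q95 = x$quantiles[[3]],
    source = x$source, n = x$n
  )
}
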