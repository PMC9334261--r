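# build an ensemble_summary; `values` (samples) or `cdf` (quadrature) enable
# downstream Kolmogorov-Smirnov comparisons
.new_ensemble_summary <- function(mean, sd, quantiles, histogram, source,
                                  n = NA_integer_, values = NULL, cdf = NULL,
                                  norm_error = NA_real_, extra = list()) {
  structure(
    c(list(
      mean = mean, sd = sd, quantiles = quantiles, histogram = histogram,
      source = source, n = n, values = values, cdf = cdf,
      norm_error = norm_error
    ), extra),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "<ensemble_summary:%s> mean = %.3f nm, sd = %s nm; q05/q50/q95 = %.2f/%.2f/%.2f nm%s\n",
    x$source, x$mean, if (is.na(x$sd)) "undefined (n < 2)" else sprintf("%.3f", x$sd),
    x$quantiles[[1]], x$quantiles[[2]], x$quantiles[[3]],
    if (is.na(x$n)) "" else sprintf(" (n = %d)", x$n)
  ))
  invisible(x)
}

.histogram_from_values <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  edges <- seq(lo, max(values) + bin_width, by = bin_width)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    count = counts,
    density = counts / (length(values) * bin_width)
  )
}

#' Boltzmann-ensemble moments of the piston coordinate
#'
#' Deterministic quadrature of the thermal distribution
#' \eqn{p(x) \propto \exp(-U(x)/k_B T)} implied by the actuator potential
#' over the admissible piston range. This is the exact counterpart of
#' [metropolis_sample()] and the model analogue of a measured TEM distance
#' distribution. Also accepts a bare potential function (a test hook for
#' closed-form cases such as the harmonic well).
#'
#' @param object An [actuator_model()], or a function `U(x)` returning
#'   potential energy in pN nm.
#' @param ... Passed to methods.
#'
#' @return An `ensemble_summary` with mean, sd, 5/50/95% quantiles, a
#'   normalized density histogram, the quadrature CDF, and the achieved
#'   normalization error.
#' @examples
#' boltzmann_moments(actuator_model()) # free autonomous 97-nt device
#' @export
boltzmann_moments <- function(object, ...) UseMethod("boltzmann_moments")

#' @rdname boltzmann_moments
#' @param resolution Grid spacing in nm for quantile/histogram evaluation
#'   (default 0.05).
#' @param bin_width Histogram bin width in nm (default 2, matching the TEM
#'   summaries).
#' @export
boltzmann_moments.actuator_model <- function(object, resolution = 0.05,
                                             bin_width = 2, ...) {
  boltzmann_moments.function(
    function(x) total_potential(object, x),
    range = c(object$x_min, object$x_max),
    thermal = object$thermal,
    resolution = resolution, bin_width = bin_width
  )
}

#' @rdname boltzmann_moments
#' @param range Length-2 numeric support `[lo, hi]` of the coordinate (nm);
#'   required for the function method.
#' @param thermal A [thermal_state()].
#' @export
boltzmann_moments.function <- function(object, range, thermal = thermal_state(),
                                       resolution = 0.05, bin_width = 2, ...) {
  stopifnot(length(range) == 2, range[2] > range[1])
  lo <- range[1]; hi <- range[2]
  kBT <- thermal$kBT
  grid <- seq(lo, hi, length.out = max(2001L, ceiling((hi - lo) / resolution) + 1L))
  u <- vapply(grid, object, numeric(1))
  if (any(!is.finite(u))) {
    stop("Potential is not finite on the support; the Boltzmann density is not integrable.",
         call. = FALSE)
  }
  u0 <- min(u)
  w <- function(x) exp(-(vapply(x, object, numeric(1)) - u0) / kBT)
  Z <- stats::integrate(w, lo, hi, rel.tol = 1e-10, subdivisions = 500L)$value
  m <- stats::integrate(function(x) x * w(x), lo, hi, rel.tol = 1e-10,
                        subdivisions = 500L)$value / Z
  v <- stats::integrate(function(x) (x - m)^2 * w(x), lo, hi, rel.tol = 1e-10,
                        subdivisions = 500L)$value / Z
  norm_error <- abs(stats::integrate(function(x) w(x) / Z, lo, hi,
                                     rel.tol = 1e-10, subdivisions = 500L)$value - 1)

  # CDF on the evaluation grid (trapezoid), for quantiles and KS comparisons
  dens <- exp(-(u - u0) / kBT) / Z
  dx <- diff(grid)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  cum <- cum / cum[length(cum)]
  cdf <- stats::approxfun(grid, cum, yleft = 0, yright = 1, ties = "ordered")
  qfun <- function(p) stats::approx(cum, grid, xout = p, ties = "ordered")$y
  quantiles <- c(q05 = qfun(0.05), q50 = qfun(0.5), q95 = qfun(0.95))

  hist_lo <- floor(lo / bin_width) * bin_width
  edges <- seq(hist_lo, hi + bin_width, by = bin_width)
  histogram <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    count = NA_integer_,
    density = (cdf(pmin(edges[-1], hi)) - cdf(pmax(edges[-length(edges)], lo))) / bin_width
  )
  .new_ensemble_summary(
    mean = m, sd = sqrt(v), quantiles = quantiles, histogram = histogram,
    source = "quadrature", cdf = cdf, norm_error = norm_error,
    extra = list(range = c(lo, hi))
  )
}

#' Seeded Metropolis sampling of the piston coordinate
#'
#' Random-walk Metropolis chain targeting the Boltzmann distribution of the
#' actuator potential, with Gaussian proposals and reflective boundaries at
#' the admissible range. The stochastic twin of [boltzmann_moments()]: on any
#' shipped model the sample mean and sd agree with quadrature within
#' Monte-Carlo error. The first 10% of `steps` are discarded as burn-in.
#'
#' @param object An [actuator_model()], or a potential function `U(x)`.
#' @param ... Passed to methods.
#'
#' @return A tibble of class `mc_sample` with columns `draw_index`, `x_nm`
#'   and attributes `acceptance_rate`, `seed`, `proposal_sd`.
#' @examples
#' s <- metropolis_sample(actuator_model(), steps = 2000, seed = 1)
#' mean(s$x_nm)
#' @export
metropolis_sample <- function(object, ...) UseMethod("metropolis_sample")

#' @rdname metropolis_sample
#' @param steps Number of recorded draws (>= 1000).
#' @param seed Integer RNG seed; required and recorded in the output.
#' @param proposal_sd Gaussian proposal standard deviation in nm (default 1).
#' @export
metropolis_sample.actuator_model <- function(object, steps = 10000L, seed,
                                             proposal_sd = 1, ...) {
  metropolis_sample.function(
    function(x) total_potential(object, x),
    range = c(object$x_min, object$x_max), thermal = object$thermal,
    steps = steps, seed = seed, proposal_sd = proposal_sd
  )
}

#' @rdname metropolis_sample
#' @param range Length-2 numeric support (nm); reflective boundaries.
#' @param thermal A [thermal_state()].
#' @export
metropolis_sample.function <- function(object, range, thermal = thermal_state(),
                                       steps = 10000L, seed, proposal_sd = 1, ...) {
  stopifnot(length(range) == 2, range[2] > range[1])
  if (missing(seed) || is.null(seed)) {
    stop("`seed` must be supplied: Metropolis samples are reproducible by seed.",
         call. = FALSE)
  }
  steps <- as.integer(steps)
  if (steps < 1000L) stop("`steps` must be at least 1000.", call. = FALSE)
  if (proposal_sd <= 0) stop("`proposal_sd` must be positive.", call. = FALSE)
  lo <- range[1]; hi <- range[2]
  kBT <- thermal$kBT
  burnin <- ceiling(0.1 * steps)
  total <- steps + burnin

  reflect <- function(x) {
    width <- hi - lo
    while (x < lo || x > hi) {
      if (x < lo) x <- lo + (lo - x)
      if (x > hi) x <- hi - (x - hi)
    }
    # guard against pathological overshoot beyond one full width
    min(max(x, lo), hi)
  }

  draws <- numeric(total)
  accepted <- 0L
  withr::with_seed(seed, {
    innov <- stats::rnorm(total, sd = proposal_sd)
    logu <- log(stats::runif(total))
    x <- (lo + hi) / 2
    ux <- object(x)
    for (i in seq_len(total)) {
      xp <- reflect(x + innov[i])
      up <- object(xp)
      if (logu[i] < (ux - up) / kBT) {
        x <- xp; ux <- up; accepted <- accepted + 1L
      }
      draws[i] <- x
    }
  })
  rate <- accepted / total
  if (rate < 0.05) {
    warning(sprintf(
      "Metropolis acceptance rate %.1f%% is very low; decrease `proposal_sd` (currently %g nm).",
      100 * rate, proposal_sd
    ), call. = FALSE)
  } else if (rate > 0.95) {
    warning(sprintf(
      "Metropolis acceptance rate %.1f%% is very high; increase `proposal_sd` (currently %g nm).",
      100 * rate, proposal_sd
    ), call. = FALSE)
  }
  out <- tibble::tibble(draw_index = seq_len(steps), x_nm = draws[(burnin + 1):total])
  class(out) <- c("mc_sample", class(out))
  attr(out, "acceptance_rate") <- rate
  attr(out, "seed") <- seed
  attr(out, "proposal_sd") <- proposal_sd
  out
}

#' Convert a Metropolis sample to a distance sample
#'
#' Reinterprets sampled piston coordinates as actuation distances so that the
#' TEM distance tooling ([summarize_distances()], [compare_to_model()])
#' applies directly.
#'
#' @param sample An `mc_sample` from [metropolis_sample()].
#' @param label Variant label (default `"mc"`).
#'
#' @return A tibble with columns `distance_nm`, `label`; attribute
#'   `source = "mc"`.
#' @export
as_distance_sample <- function(sample, label = "mc") {
  stopifnot(inherits(sample, "mc_sample"))
  out <- tibble::tibble(distance_nm = sample$x_nm, label = label)
  attr(out, "source") <- "mc"
  out
}
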