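# Calibrated default span of the one-coordinate geometry map (nm).
# Obtained once with calibrate_geometry() against the two published anchor
# forces of the autonomous 97-nt device (1.6 pN at k_protein = 0.1 pN/nm,
# 30 pN at 20 pN/nm) under the constraint top_offset >= 0; the fit lands on
# the boundary top_offset = 0 with residual 0.075 pN.
.default_span_D <- 32.1794811578

#' One-coordinate geometry map of the piston
#'
#' The piston coordinate `x` (distance between the bottom of the piston and
#' the bottom of the cylinder, nm) determines both connector extensions
#' through a fixed end-to-end budget `span_D`:
#' `e_top(x) = x + top_offset` and, in autonomous mode,
#' `e_bot(x) = span_D - x + bottom_offset`. In remote (hybridized-connector)
#' mode the antagonistic bottom set instead engages as the piston extends,
#' `e_bot(x) = max(0, x - span_D + bottom_offset)`, with `span_D` acting as
#' the slack budget stored in the reservoir loops.
#'
#' @param span_D Total end-to-end budget (autonomous) or slack budget
#'   (remote), nm; non-negative.
#' @param top_offset,bottom_offset Additive offsets in nm; non-negative.
#'
#' @return An object of class `geometry_map`.
#' @seealso [calibrated_geometry()] for the shipped default.
#' @export
geometry_map <- function(span_D, top_offset = 0, bottom_offset = 0) {
  if (!is.numeric(span_D) || length(span_D) != 1 || span_D < 0) {
    stop("`span_D` must be a single non-negative length (nm).", call. = FALSE)
  }
  if (top_offset < 0 || bottom_offset < 0) {
    stop("Geometry offsets must be non-negative (connector extensions cannot be negative).",
         call. = FALSE)
  }
  structure(
    list(span_D = span_D, top_offset = top_offset, bottom_offset = bottom_offset),
    class = "geometry_map"
  )
}

#' Shipped calibrated geometry for the autonomous device
#'
#' The default geometry map frozen from a one-time least-squares calibration
#' of (`span_D`, `top_offset`) to the two published anchor forces of the
#' autonomous 97-nt device: 1.6 pN at k_protein = 0.1 pN/nm and 30 pN at
#' 20 pN/nm. Re-run [calibrate_geometry()] to reproduce it.
#'
#' @return A `geometry_map` with `span_D` = 32.1795 nm and zero offsets.
#' @export
calibrated_geometry <- function() {
  geometry_map(span_D = .default_span_D, top_offset = 0, bottom_offset = 0)
}

#' Linear spring model of the molecular target
#'
#' @param k Spring constant k_protein in pN/nm; non-negative.
#' @param rest_position Unstressed piston coordinate in nm (default 0:
#'   the target is relaxed at full retraction).
#'
#' @return An object of class `protein_spring`.
#' @export
protein_spring <- function(k, rest_position = 0) {
  if (!is.numeric(k) || length(k) != 1 || k < 0) {
    stop("`k` must be a single non-negative stiffness (pN/nm).", call. = FALSE)
  }
  structure(list(k = k, rest_position = rest_position), class = "protein_spring")
}

#' Device-level effective stiffnesses from coarse-grained simulation
#'
#' Linearized whole-device stiffnesses reported for 97-unit connectors:
#' 8.0e-3 N/m (= 8.0 pN/nm) double-stranded and 3.0e-3 N/m (= 3.0 pN/nm)
#' single-stranded. Used as constants; the coarse-grained simulations
#' themselves are out of scope.
#'
#' @param k_eff_ds,k_eff_ss Effective stiffnesses in pN/nm; positive.
#' @return An object of class `effective_stiffness`.
#' @export
effective_stiffness <- function(k_eff_ds = 8.0, k_eff_ss = 3.0) {
  if (k_eff_ds <= 0 || k_eff_ss <= 0) {
    stop("Effective stiffnesses must be positive (pN/nm).", call. = FALSE)
  }
  structure(list(k_eff_ds = k_eff_ds, k_eff_ss = k_eff_ss),
            class = "effective_stiffness")
}

#' Assemble an actuator model
#'
#' Composes top and bottom connector sets, the geometry map, a linear protein
#' spring, and the thermal state into a single force-balance model of the
#' piston-cylinder device.
#'
#' Modes:
#' * `"autonomous_ss"` - both connector sets are entropic worm-like-chain
#'   springs pulling against each other and the protein spring.
#' * `"remote_ds_rigid"` - the hybridized top connectors are treated as rigid
#'   rods at their contour length (used for anticipated-extension predictions).
#' * `"remote_ds_effective"` - the hybridized top set is a linear spring with
#'   the device-level effective stiffness `k_eff_ds`, anchored at its contour
#'   length; the bottom worm-like-chain set engages once the slack budget is
#'   used up and resists extension.
#'
#' @param top,bottom [polymer_spec()] for the two connector sets.
#' @param n_top,n_bottom Connector copy numbers (default 6 each).
#' @param geometry A [geometry_map()]; defaults to the shipped calibration.
#' @param protein A [protein_spring()]; defaults to a free piston (k = 0).
#' @param thermal A [thermal_state()].
#' @param mode One of `"autonomous_ss"`, `"remote_ds_rigid"`,
#'   `"remote_ds_effective"`.
#' @param k_eff An [effective_stiffness()].
#'
#' @return An object of class `actuator_model` with resolved admissible
#'   piston range `x_min`, `x_max`.
#' @examples
#' m <- actuator_model(protein = protein_spring(0.1))
#' solve_equilibrium(m)
#' @export
actuator_model <- function(top = polymer_spec(97, "single"),
                           bottom = polymer_spec(97, "single"),
                           n_top = 6, n_bottom = 6,
                           geometry = calibrated_geometry(),
                           protein = protein_spring(0),
                           thermal = thermal_state(),
                           mode = c("autonomous_ss", "remote_ds_rigid", "remote_ds_effective"),
                           k_eff = effective_stiffness()) {
  mode <- match.arg(mode)
  stopifnot(
    inherits(top, "polymer_spec"), inherits(bottom, "polymer_spec"),
    inherits(geometry, "geometry_map"), inherits(protein, "protein_spring"),
    inherits(thermal, "thermal_state"), inherits(k_eff, "effective_stiffness")
  )
  if (n_top < 1 || n_bottom < 1) {
    stop("`n_top` and `n_bottom` must be at least 1.", call. = FALSE)
  }
  if (mode != "autonomous_ss" && top$strandedness != "double") {
    stop("Remote modes require double-stranded top connectors.", call. = FALSE)
  }
  eps <- 1e-9
  c1 <- geometry$top_offset
  c2 <- geometry$bottom_offset
  D <- geometry$span_D
  if (mode == "remote_ds_effective") {
    # top term is quadratic (no WLC domain limit); bottom engages above the slack budget
    x_min <- 0
    x_max <- D - c2 + bottom$contour_length * (1 - eps)
  } else {
    x_min <- max(0, -c1, D + c2 - bottom$contour_length * (1 - eps))
    x_max <- min(top$contour_length * (1 - eps) - c1, D + c2, D)
  }
  if (x_min >= x_max) {
    stop("Geometry admits no piston range: check span_D, offsets and contour lengths.",
         call. = FALSE)
  }
  structure(
    list(
      top = top, bottom = bottom, n_top = n_top, n_bottom = n_bottom,
      geometry = geometry, protein = protein, thermal = thermal,
      mode = mode, k_eff = k_eff, x_min = x_min, x_max = x_max
    ),
    class = "actuator_model"
  )
}

#' @export
print.actuator_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<actuator_model> mode %s\n",
      "  top: %d x %s-stranded Lc %.2f nm | bottom: %d x %s-stranded Lc %.2f nm\n",
      "  geometry: span_D %.3f nm, offsets (%.2f, %.2f); x in [%.3f, %.3f] nm\n",
      "  protein spring k = %g pN/nm (rest %.2f nm), T = %.2f K\n"
    ),
    x$mode, x$n_top, x$top$strandedness, x$top$contour_length,
    x$n_bottom, x$bottom$strandedness, x$bottom$contour_length,
    x$geometry$span_D, x$geometry$top_offset, x$geometry$bottom_offset,
    x$x_min, x$x_max, x$protein$k, x$protein$rest_position, x$thermal$temperature
  ))
  invisible(x)
}

# connector extensions at piston coordinate x (no domain checks)
.extensions <- function(model, x) {
  g <- model$geometry
  if (model$mode == "remote_ds_effective") {
    list(top = x + g$top_offset, bot = pmax(0, x - g$span_D + g$bottom_offset))
  } else {
    list(top = x + g$top_offset, bot = g$span_D - x + g$bottom_offset)
  }
}

#' Total potential energy of the actuator at a piston coordinate
#'
#' Sum of connector elastic energies and the protein-spring energy:
#' `U(x) = n_top E_top(e_top(x)) + n_bottom E_bot(e_bot(x)) +
#' 0.5 k (x - rest)^2`. In `remote_ds_effective` mode the top term is the
#' quadratic `0.5 k_eff_ds (e_top(x) - Lc_top)^2`; in `remote_ds_rigid` mode
#' the top set is a constraint and contributes no energy.
#'
#' @param model An [actuator_model()].
#' @param x Piston coordinate(s) in nm, inside `[x_min, x_max]`.
#'
#' @return Potential energy(ies) in pN nm.
#' @export
total_potential <- function(model, x) {
  stopifnot(inherits(model, "actuator_model"))
  if (any(x < model$x_min - 1e-12) || any(x > model$x_max + 1e-12)) {
    stop(sprintf("`x` must lie in the admissible piston range [%.4f, %.4f] nm.",
                 model$x_min, model$x_max), call. = FALSE)
  }
  e <- .extensions(model, x)
  pr <- model$protein
  u_protein <- 0.5 * pr$k * (x - pr$rest_position)^2
  u_top <- switch(model$mode,
    autonomous_ss = model$n_top * wlc_energy(model$top, e$top, model$thermal),
    remote_ds_effective = 0.5 * model$k_eff$k_eff_ds * (e$top - model$top$contour_length)^2,
    remote_ds_rigid = 0
  )
  u_bot <- model$n_bottom * wlc_energy(model$bottom, e$bot, model$thermal)
  u_top + u_bot + u_protein
}

# dU/dx, the negative of the total force on the piston
.potential_gradient <- function(model, x) {
  e <- .extensions(model, x)
  pr <- model$protein
  g_protein <- pr$k * (x - pr$rest_position)
  th <- model$thermal
  if (model$mode == "autonomous_ss") {
    model$n_top * wlc_force(model$top, e$top, th) -
      model$n_bottom * wlc_force(model$bottom, e$bot, th) + g_protein
  } else if (model$mode == "remote_ds_effective") {
    g_bot <- ifelse(e$bot > 0, model$n_bottom * wlc_force(model$bottom, pmax(e$bot, 0), th), 0)
    model$k_eff$k_eff_ds * (e$top - model$top$contour_length) + g_bot + g_protein
  } else {
    stop("Potential gradient is undefined in rigid mode (top set is a constraint).",
         call. = FALSE)
  }
}

#' Solve the mechanical equilibrium of the actuator
#'
#' Finds the piston coordinate `x_eq` minimizing [total_potential()] by a
#' bracketed root of its derivative, after a numeric strict-convexity check
#' on the admissible interval. In `remote_ds_rigid` mode the equilibrium is
#' the contour-length constraint point `x_eq = Lc_top - top_offset`.
#'
#' @param model An [actuator_model()].
#'
#' @return An object of class `equilibrium`: list with `x_eq` (nm),
#'   `force_on_protein` (pN, `k (x_eq - rest)`), `residual` (pN, |dU/dx| at
#'   the solution), and `converged`. A boundary solution (no interior
#'   stationary point) is returned with `converged = FALSE`.
#' @examples
#' solve_equilibrium(actuator_model(protein = protein_spring(0.1)))
#' @export
solve_equilibrium <- function(model) {
  stopifnot(inherits(model, "actuator_model"))
  pr <- model$protein
  if (model$mode == "remote_ds_rigid") {
    x_eq <- model$top$contour_length - model$geometry$top_offset
    res <- structure(
      list(x_eq = x_eq, force_on_protein = pr$k * (x_eq - pr$rest_position),
           residual = 0, converged = TRUE, model = model),
      class = "equilibrium"
    )
    return(res)
  }
  lo <- model$x_min + 1e-12
  hi <- model$x_max - 1e-12
  # numeric convexity check: dU/dx must be increasing across the interval
  grid <- seq(lo, hi, length.out = 41)
  dg <- diff(.potential_gradient(model, grid))
  if (any(dg < -1e-8)) {
    stop("Potential is not strictly convex on the admissible interval; equilibrium undefined.",
         call. = FALSE)
  }
  g_lo <- .potential_gradient(model, lo)
  g_hi <- .potential_gradient(model, hi)
  if (g_lo >= 0) {
    x_eq <- lo; converged <- FALSE
  } else if (g_hi <= 0) {
    x_eq <- hi; converged <- FALSE
  } else {
    x_eq <- stats::uniroot(function(x) .potential_gradient(model, x),
                           interval = c(lo, hi), tol = 1e-13, maxiter = 2000L)$root
    converged <- TRUE
  }
  residual <- abs(.potential_gradient(model, x_eq))
  structure(
    list(x_eq = x_eq, force_on_protein = pr$k * (x_eq - pr$rest_position),
         residual = residual, converged = converged && residual < 1e-6,
         model = model),
    class = "equilibrium"
  )
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf(
    "<equilibrium> x_eq = %.4f nm, force on protein = %.4f pN (residual %.2e pN%s)\n",
    x$x_eq, x$force_on_protein, x$residual,
    if (x$converged) "" else "; boundary / not converged"
  ))
  invisible(x)
}

#' Equilibrium force across a grid of protein stiffnesses
#'
#' Solves the actuator equilibrium for each protein-spring constant in
#' `k_grid` and tabulates the applied force. Reproduces the published force
#' span of the autonomous 97-nt device (about 1.6 pN at 0.1 pN/nm up to
#' 30 pN at 20 pN/nm) with the shipped calibrated geometry.
#'
#' @param model An [actuator_model()]; its own protein spring constant is
#'   ignored in favour of `k_grid` (rest position is kept).
#' @param k_grid Non-decreasing vector of protein stiffnesses in pN/nm.
#'
#' @return A tibble of class `force_profile_k` with columns `k_protein`,
#'   `x_eq`, `force_pN`, `residual`, `converged`.
#' @export
force_vs_kprotein <- function(model, k_grid) {
  stopifnot(inherits(model, "actuator_model"))
  if (any(k_grid < 0)) stop("`k_grid` must be non-negative.", call. = FALSE)
  if (is.unsorted(k_grid)) stop("`k_grid` must be sorted increasing.", call. = FALSE)
  rest <- model$protein$rest_position
  out <- purrr::map_dfr(k_grid, function(k) {
    m <- model
    m$protein <- protein_spring(k, rest)
    eq <- solve_equilibrium(m)
    tibble::tibble(
      k_protein = k, x_eq = eq$x_eq, force_pN = eq$force_on_protein,
      residual = eq$residual, converged = eq$converged
    )
  })
  class(out) <- c("force_profile_k", class(out))
  out
}

#' Calibrate free geometry parameters to target forces
#'
#' Least-squares fit of the free geometry parameters (by default `span_D` and
#' `top_offset`) so that the equilibrium force at given protein stiffnesses
#' matches target values. The shipped default geometry was produced by this
#' routine with the two published anchor points of the autonomous 97-nt
#' device; `top_offset` is constrained to be non-negative (connector
#' extensions cannot be negative), and the default fit lands on that boundary
#' with residual 0.075 pN.
#'
#' @param model An [actuator_model()] providing everything but the free
#'   geometry parameters.
#' @param targets A data frame with columns `k_protein` (pN/nm) and `force`
#'   (pN); at least two rows. Defaults to the two published anchors
#'   (0.1 -> 1.6 pN, 20 -> 30 pN).
#' @param free Character vector of free parameters among `"span_D"`,
#'   `"top_offset"`.
#' @param max_residual Largest acceptable per-target force residual (pN)
#'   before the fit is declared non-convergent; default 0.1.
#'
#' @return A [geometry_map()] carrying a `calibration` attribute (targets,
#'   fitted forces, residuals, fitted parameters).
#' @export
calibrate_geometry <- function(model,
                               targets = tibble::tibble(k_protein = c(0.1, 20),
                                                        force = c(1.6, 30)),
                               free = c("span_D", "top_offset"),
                               max_residual = 0.1) {
  stopifnot(inherits(model, "actuator_model"))
  free <- match.arg(free, choices = c("span_D", "top_offset"), several.ok = TRUE)
  targets <- as.data.frame(targets)
  if (!all(c("k_protein", "force") %in% names(targets))) {
    stop("`targets` needs columns `k_protein` and `force`.", call. = FALSE)
  }
  if (nrow(targets) < 2) {
    stop("At least two (k_protein, force) targets are required to calibrate the geometry.",
         call. = FALSE)
  }
  g0 <- model$geometry
  start <- c(span_D = g0$span_D, top_offset = g0$top_offset)[free]
  lower <- c(span_D = 1e-3, top_offset = 0)[free]
  upper <- c(span_D = model$top$contour_length + model$bottom$contour_length,
             top_offset = model$top$contour_length / 2)[free]

  predict_forces <- function(p) {
    g <- g0
    for (nm in names(p)) g[[nm]] <- unname(p[nm])
    geom <- tryCatch(geometry_map(g$span_D, g$top_offset, g$bottom_offset),
                     error = function(e) NULL)
    if (is.null(geom)) return(NULL)
    vapply(targets$k_protein, function(k) {
      m <- tryCatch(
        actuator_model(model$top, model$bottom, model$n_top, model$n_bottom,
                       geom, protein_spring(k, model$protein$rest_position),
                       model$thermal, model$mode, model$k_eff),
        error = function(e) NULL
      )
      if (is.null(m)) return(NA_real_)
      eq <- tryCatch(solve_equilibrium(m), error = function(e) NULL)
      if (is.null(eq)) NA_real_ else eq$force_on_protein
    }, numeric(1))
  }
  objective <- function(p) {
    names(p) <- free
    f <- predict_forces(p)
    if (is.null(f) || any(is.na(f))) return(1e8)
    sum((f - targets$force)^2)
  }
  fit <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500L, factr = 1e4))
  # polish with a derivative-free pass (L-BFGS-B can stall on bound-active fits)
  fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000L, reltol = 1e-14))
  par <- pmin(pmax(fit2$par, lower), upper)
  names(par) <- free
  fitted <- predict_forces(par)
  residuals <- fitted - targets$force
  if (any(is.na(fitted)) || max(abs(residuals)) > max_residual) {
    stop(sprintf(
      "Geometry calibration did not converge; force residuals (pN): %s",
      paste(sprintf("%.3f", residuals), collapse = ", ")
    ), call. = FALSE)
  }
  g <- g0
  for (nm in free) g[[nm]] <- unname(par[nm])
  out <- geometry_map(g$span_D, g$top_offset, g$bottom_offset)
  attr(out, "calibration") <- list(
    targets = tibble::as_tibble(targets),
    fitted_force = fitted,
    residuals = residuals,
    parameters = par
  )
  out
}
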