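#' Specify a DNA connector as a worm-like chain
#'
#' A connector is described by its unit count (nucleotides for single-stranded,
#' base pairs for double-stranded DNA), the helical rise per unit, and the
#' persistence length. Defaults follow the standard values for the two
#' strandedness regimes: single-stranded DNA is flexible (persistence length
#' about 1 nm, rise 0.63 nm/nt) while hybridized double-stranded DNA is stiff
#' (persistence length about 50 nm at sodium concentrations above 10 mM,
#' rise 0.34 nm/bp).
#'
#' @param n_units Number of chain units (nt or bp); positive.
#' @param strandedness `"single"` or `"double"`.
#' @param rise_per_unit Rise per unit in nm; defaults to 0.63 (single) or
#'   0.34 (double).
#' @param persistence_length Persistence length in nm; defaults to 1 (single)
#'   or 50 (double).
#'
#' @return An object of class `polymer_spec` with fields `n_units`,
#'   `rise_per_unit`, `contour_length`, `persistence_length`, `strandedness`.
#' @examples
#' polymer_spec(97)                        # 97-nt ssDNA connector, Lc = 61.11 nm
#' polymer_spec(97, "double")              # 97-bp dsDNA connector, Lc = 32.98 nm
#' @export
polymer_spec <- function(n_units,
                         strandedness = c("single", "double"),
                         rise_per_unit = NULL,
                         persistence_length = NULL) {
  strandedness <- match.arg(strandedness)
  if (!is.numeric(n_units) || length(n_units) != 1 || n_units <= 0) {
    stop("`n_units` must be a single positive count.", call. = FALSE)
  }
  if (is.null(rise_per_unit)) {
    rise_per_unit <- switch(strandedness, single = 0.63, double = 0.34)
  }
  if (is.null(persistence_length)) {
    persistence_length <- switch(strandedness, single = 1, double = 50)
  }
  if (rise_per_unit <= 0) stop("`rise_per_unit` must be positive.", call. = FALSE)
  if (persistence_length <= 0) stop("`persistence_length` must be positive.", call. = FALSE)
  structure(
    list(
      n_units = n_units,
      rise_per_unit = rise_per_unit,
      contour_length = n_units * rise_per_unit,
      persistence_length = persistence_length,
      strandedness = strandedness
    ),
    class = "polymer_spec"
  )
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf(
    "<polymer_spec> %s-stranded, %g units: Lc = %.2f nm, Lp = %g nm (rise %g nm/unit)\n",
    x$strandedness, x$n_units, x$contour_length, x$persistence_length, x$rise_per_unit
  ))
  invisible(x)
}

.check_extension <- function(spec, z) {
  if (any(!is.finite(z))) stop("Extension `z` must be finite.", call. = FALSE)
  if (any(z < 0)) {
    stop("Extension `z` must be non-negative (end-to-end distance in nm).",
         call. = FALSE)
  }
  if (any(z >= spec$contour_length)) {
    stop(sprintf(
      "Extension `z` must stay strictly below the contour length Lc = %.4f nm (worm-like-chain force diverges at Lc).",
      spec$contour_length
    ), call. = FALSE)
  }
  invisible(z)
}

#' Worm-like-chain force at a given extension
#'
#' Entropic restoring force of a connector held at end-to-end extension `z`,
#' using the Marko-Siggia interpolation
#' \deqn{F(z) = \frac{k_B T}{L_p}\left[\frac{1}{4}(1 - z/L_c)^{-2} -
#'   \frac{1}{4} + \frac{z}{L_c}\right],}
#' which is exact in the small- and high-force limits and accurate to a few
#' percent in between. The force is zero at `z = 0`, strictly increasing, and
#' diverges as `z` approaches the contour length.
#'
#' @param spec A [polymer_spec()].
#' @param z Extension(s) in nm; `0 <= z < contour_length`.
#' @param thermal A [thermal_state()].
#'
#' @return Force(s) in pN, same length as `z`.
#' @examples
#' wlc_force(polymer_spec(97), 30) # ~4.93 pN for the 97-nt ss connector
#' @seealso [wlc_extension_at_force()], [wlc_stiffness()], [wlc_energy()]
#' @export
wlc_force <- function(spec, z, thermal = thermal_state()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermal, "thermal_state"))
  .check_extension(spec, z)
  t <- z / spec$contour_length
  (thermal$kBT / spec$persistence_length) * (0.25 * (1 - t)^-2 - 0.25 + t)
}

#' Worm-like-chain extension at a given force
#'
#' Numeric inverse of [wlc_force()]: the extension at which the chain's
#' entropic tension balances an applied force `F`. Solved by bracketed root
#' finding on `[0, Lc)` to an absolute tolerance of 1e-9 nm.
#'
#' @param spec A [polymer_spec()].
#' @param force Applied force(s) in pN; non-negative.
#' @inheritParams wlc_force
#'
#' @return Extension(s) in nm.
#' @examples
#' wlc_extension_at_force(polymer_spec(97), 4.93) # ~30 nm
#' @export
wlc_extension_at_force <- function(spec, force, thermal = thermal_state()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermal, "thermal_state"))
  if (any(!is.finite(force)) || any(force < 0)) {
    stop("`force` must be non-negative and finite (pN).", call. = FALSE)
  }
  Lc <- spec$contour_length
  vapply(force, function(f) {
    if (f == 0) return(0)
    # upper bracket from the high-force asymptote z/Lc ~ 1 - 0.5*sqrt(kBT/(F Lp))
    hi <- Lc * min(1 - 1e-12, 1 - 0.25 * sqrt(thermal$kBT / (f * spec$persistence_length)))
    hi <- max(hi, Lc * 1e-6)
    while (wlc_force(spec, hi, thermal) < f) hi <- (hi + Lc) / 2
    stats::uniroot(
      function(z) wlc_force(spec, z, thermal) - f,
      interval = c(0, hi), tol = 1e-9, maxiter = 1000L
    )$root
  }, numeric(1))
}

#' Worm-like-chain elastic energy
#'
#' Potential energy stored in a connector stretched to extension `z`: the
#' antiderivative of [wlc_force()] with `E(0) = 0`,
#' \deqn{E(z) = \frac{k_B T}{L_p}\left[\frac{z^2}{2 L_c} +
#'   \frac{L_c}{4(1 - z/L_c)} - \frac{L_c}{4} - \frac{z}{4}\right].}
#'
#' @inheritParams wlc_force
#' @return Energy in pN nm, same length as `z`.
#' @export
wlc_energy <- function(spec, z, thermal = thermal_state()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermal, "thermal_state"))
  .check_extension(spec, z)
  Lc <- spec$contour_length
  (thermal$kBT / spec$persistence_length) *
    (z^2 / (2 * Lc) + Lc / (4 * (1 - z / Lc)) - Lc / 4 - z / 4)
}

#' Worm-like-chain local stiffness
#'
#' Analytic derivative dF/dz of [wlc_force()]:
#' \deqn{k(z) = \frac{k_B T}{L_p L_c}\left[\frac{1}{2}(1 - z/L_c)^{-3} + 1\right].}
#' At zero extension this reduces to the entropic-spring constant
#' \eqn{3 k_B T / (2 L_p L_c)}.
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm, same length as `z`.
#' @export
wlc_stiffness <- function(spec, z, thermal = thermal_state()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermal, "thermal_state"))
  .check_extension(spec, z)
  t <- z / spec$contour_length
  (thermal$kBT / (spec$persistence_length * spec$contour_length)) *
    (0.5 * (1 - t)^-3 + 1)
}

#' Tabulated force-extension curve
#'
#' Evaluates force and stiffness on a grid of extensions, for plotting or CSV
#' export.
#'
#' @param spec A [polymer_spec()].
#' @param extensions Extension grid in nm; defaults to 200 points spanning
#'   `[0, 0.99 Lc]`.
#' @inheritParams wlc_force
#'
#' @return A tibble with columns `extension_nm`, `force_pN`,
#'   `stiffness_pN_per_nm`, of class `wlc_profile`.
#' @examples
#' head(wlc_profile(polymer_spec(97)))
#' @export
wlc_profile <- function(spec, extensions = NULL, thermal = thermal_state()) {
  if (is.null(extensions)) {
    extensions <- seq(0, 0.99 * spec$contour_length, length.out = 200)
  }
  out <- tibble::tibble(
    extension_nm = extensions,
    force_pN = wlc_force(spec, extensions, thermal),
    stiffness_pN_per_nm = wlc_stiffness(spec, extensions, thermal)
  )
  class(out) <- c("wlc_profile", class(out))
  attr(out, "spec") <- spec
  out
}
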