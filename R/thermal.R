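# Boltzmann constant in pN nm / K
.kB <- 0.0138065

#' Thermal state of the actuator bath
#'
#' Bundles the bath temperature with the derived thermal energy
#' \eqn{k_B T} in pN nm, the unit system used throughout the package.
#' The default, 296.15 K (23 degrees C), is the temperature at which the
#' device was characterized.
#'
#' @param temperature Bath temperature in kelvin. Must be positive.
#'
#' @return An object of class `thermal_state`: a list with elements
#'   `temperature` (K) and `kBT` (pN nm).
#' @examples
#' thermal_state()$kBT # ~4.09 pN nm at 23 C
#' @export
thermal_state <- function(temperature = 296.15) {
  if (!is.numeric(temperature) || length(temperature) != 1 || !is.finite(temperature) ||
      temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin).", call. = FALSE)
  }
  structure(
    list(temperature = temperature, kBT = .kB * temperature),
    class = "thermal_state"
  )
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> T = %.2f K, kBT = %.4f pN nm\n", x$temperature, x$kBT))
  invisible(x)
}
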