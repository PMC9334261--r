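#' Anticipated piston extension of a hybridized connector
#'
#' Rigid-rod (contour-length) prediction of the distance the piston tip moves
#' when a connector of `n_bp` base pairs is hybridized: `n_bp x 0.34 nm`,
#' rounded to the nearest integer nanometre. Reproduces the anticipated
#' distances 10, 20 and 33 nm for 30-, 60- and 97-bp connectors.
#'
#' @param n_bp Connector length(s) in base pairs; positive.
#' @param rise_per_bp Helical rise in nm/bp (default 0.34).
#'
#' @return Integer-rounded extension(s) in nm.
#' @examples
#' predict_anticipated_extension(c(30, 60, 97)) # 10 20 33
#' @export
predict_anticipated_extension <- function(n_bp, rise_per_bp = 0.34) {
  if (any(n_bp <= 0)) stop("`n_bp` must be positive.", call. = FALSE)
  round(n_bp * rise_per_bp)
}

#' Hairpin rupture-force benchmark
#'
#' Linear-approximation force exerted when the device is deformed from its
#' equilibrium by a tethering hairpin: `k_eff x deformation`. With the
#' double-stranded effective stiffness 8.0 pN/nm and the estimated 5.3 nm
#' deformation this gives 42 pN (2 significant figures), exceeding the
#' hairpin's unzipping force F_1/2 of about 20 pN.
#'
#' @param k_eff Effective device stiffness in pN/nm (default 8.0,
#'   double-stranded 97-unit connectors).
#' @param deformation Deformation from equilibrium in nm (default 5.3).
#' @param f_half Hairpin equilibrium unzipping force in pN (default 20).
#'
#' @return A one-row tibble with `k_eff_pN_per_nm`, `deformation_nm`,
#'   `force_pN`, `force_2sf` (2 significant figures), `f_half_pN`,
#'   `exceeds_f_half`.
#' @examples
#' hairpin_force() # 42.4 pN, reported as 42, exceeds F_1/2
#' @export
hairpin_force <- function(k_eff = 8.0, deformation = 5.3, f_half = 20) {
  if (deformation < 0) stop("`deformation` must be non-negative.", call. = FALSE)
  force <- k_eff * deformation
  tibble::tibble(
    k_eff_pN_per_nm = k_eff,
    deformation_nm = deformation,
    force_pN = force,
    force_2sf = signif(force, 2),
    f_half_pN = f_half,
    exceeds_f_half = force > f_half
  )
}

#' Two-state hairpin opening probability under force
#'
#' Logistic (two-state Boltzmann) model of a DNA hairpin under load: the
#' probability of the unzipped state is
#' `1 / (1 + exp(-(F - F_1/2) dz / kBT))`, where `dz` is the opening
#' distance. At `F = F_1/2` the hairpin spends half its time unzipped.
#'
#' @param force Applied force(s) in pN; non-negative.
#' @param f_half Equilibrium unzipping force in pN (default 20).
#' @param delta_z_open Opening distance in nm (default 10, a typical hairpin
#'   opening length; configuration-exposed).
#' @param thermal A [thermal_state()].
#'
#' @return Opening probability(ies) in (0, 1).
#' @examples
#' hairpin_open_probability(20)  # 0.5 by definition of F_1/2
#' hairpin_open_probability(42)  # essentially 1
#' @export
hairpin_open_probability <- function(force, f_half = 20, delta_z_open = 10,
                                     thermal = thermal_state()) {
  if (any(force < 0)) stop("`force` must be non-negative.", call. = FALSE)
  stats::plogis((force - f_half) * delta_z_open / thermal$kBT)
}

#' Membrane indentation under the landing legs
#'
#' Linear indentation model: the device sinks about 1.0 angstrom (0.1 nm)
#' into the membrane per piconewton of force it exerts.
#'
#' @param force Force(s) in pN; non-negative.
#' @param coeff Indentation coefficient in nm/pN (default 0.1).
#'
#' @return Indentation(s) in nm.
#' @examples
#' membrane_indentation(10) # 1 nm
#' @export
membrane_indentation <- function(force, coeff = 0.1) {
  if (any(force < 0)) stop("`force` must be non-negative.", call. = FALSE)
  coeff * force
}

#' Effective actuation distance corrected for membrane indentation
#'
#' Subtracts the membrane indentation from a nominal actuation distance,
#' floored at zero.
#'
#' @param d Nominal actuation distance(s) in nm.
#' @param force Force(s) in pN.
#' @inheritParams membrane_indentation
#'
#' @return Effective distance(s) in nm.
#' @examples
#' effective_distance(17.7, 5) # 17.2 nm
#' @export
effective_distance <- function(d, force, coeff = 0.1) {
  pmax(0, d - membrane_indentation(force, coeff))
}

#' Thermal positioning precision of parallel connectors
#'
#' Equipartition standard deviation of the piston position when held by `n`
#' parallel connectors of individual stiffness `k_single`:
#' `sqrt(kBT / (n k_single))`. Stiffening by parallelization improves the
#' positioning precision as `1/sqrt(n)`.
#'
#' @param n_connectors Number of parallel connectors; at least 1.
#' @param k_single Stiffness of a single connector in pN/nm; positive.
#' @param thermal A [thermal_state()].
#'
#' @return Positional standard deviation in nm.
#' @examples
#' positioning_sd(6, 8 / 6) # ~0.71 nm for the 8 pN/nm device
#' @export
positioning_sd <- function(n_connectors, k_single, thermal = thermal_state()) {
  if (any(n_connectors < 1)) stop("`n_connectors` must be at least 1.", call. = FALSE)
  if (any(k_single <= 0)) stop("`k_single` must be positive (pN/nm).", call. = FALSE)
  sqrt(thermal$kBT / (n_connectors * k_single))
}
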