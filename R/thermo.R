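#' @keywords internal
"_PACKAGE"

#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' The MD-package convention value used throughout: 0.0019872.
#' @export
KB_KCAL <- 0.0019872

#' Coulomb constant in kcal mol^-1 Angstrom e^-2
#' @export
COULOMB_KCAL <- 332.0636

AVOGADRO <- 6.02214076e23

#' Thermodynamic state
#'
#' Bundles the temperature with the Boltzmann constant and the inverse
#' temperature beta = 1/(kB T) used by every free-energy expression in the
#' package.
#'
#' @param temperature Absolute temperature in kelvin. 300 K is the default
#'   used for all free-energy work; 310 K is typical for contact-stability
#'   simulations.
#' @param kB Boltzmann constant in kcal mol^-1 K^-1.
#' @return An object of class `thermo_state` with fields `temperature`,
#'   `kB`, `kT` (kcal mol^-1) and `beta` (mol kcal^-1).
#' @examples
#' th <- thermo_state(300)
#' th$kT  # ~0.596 kcal/mol
#' @export
thermo_state <- function(temperature = 300, kB = KB_KCAL) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive and finite, got ", temperature)
  kT <- kB * temperature
  structure(
    list(temperature = temperature, kB = kB, kT = kT, beta = 1 / kT),
    class = "thermo_state"
  )
}

#' Volume per molecule at the standard 1 mol/L concentration
#'
#' The standard concentration C0 = 1 mol L^-1 corresponds to one molecule
#' per 1660.539 cubic Angstroms; its inverse enters the separation term of
#' the geometric route as C0 = 1/1660.539 A^-3.
#'
#' @return Volume in Angstrom^3 (about 1660.539).
#' @export
standard_state_volume <- function() {
  1e27 / AVOGADRO
}

#' Convert a standard binding free energy to a dissociation constant
#'
#' K_D = C0 * exp(dG0 / kT) with C0 the 1 mol/L standard concentration, so
#' dG0 = 0 maps to K_D = 1 mol/L and more negative free energies to
#' stronger (smaller) dissociation constants.
#'
#' @param deltaG0 Standard binding free energy in kcal mol^-1.
#' @param thermo A [thermo_state()].
#' @return Dissociation constant in mol L^-1.
#' @seealso [kd_to_deltaG()]
#' @export
deltaG_to_kd <- function(deltaG0, thermo = thermo_state()) {
  stopifnot(is.finite(deltaG0))
  exp(deltaG0 * thermo$beta)
}

#' Convert a dissociation constant to a standard binding free energy
#'
#' Inverse of [deltaG_to_kd()]; round-trips to near machine precision.
#'
#' @param kd Dissociation constant in mol L^-1 (positive).
#' @param thermo A [thermo_state()].
#' @return Standard binding free energy in kcal mol^-1.
#' @export
kd_to_deltaG <- function(kd, thermo = thermo_state()) {
  stopifnot(is.finite(kd), kd > 0)
  thermo$kT * log(kd)
}
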