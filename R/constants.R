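# Physical constants used throughout.  Energies are kcal/mol, distances
# Angstrom, angles degrees at the interface (radians internally), charges in
# units of the elementary charge.

.COULOMB <- 332.0716        # kcal * A / (mol * e^2)
.KB <- 0.0019872041         # kcal / mol / K
.DEFAULT_T <- 303.15        # K, the simulation temperature of all scenarios
.STD_VOLUME <- 1661         # A^3 per molecule at the 1 M standard state

#' Physical constants used by pumpsel
#'
#' Returns the fixed constants of the package: the Coulomb constant in
#' kcal*A/(mol*e^2), the Boltzmann constant in kcal/mol/K, the default
#' simulation temperature in K, and the standard-state volume (one molecule
#' per 1661 A^3, i.e. a 1 M reference concentration).
#'
#' @return A named list with elements `coulomb`, `kB`, `temperature`,
#'   `standard_volume`.
#' @export
#' @examples
#' pump_constants()$kB * pump_constants()$temperature  # RT at 303.15 K
pump_constants <- function() {
  list(coulomb = .COULOMB, kB = .KB, temperature = .DEFAULT_T,
       standard_volume = .STD_VOLUME)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
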