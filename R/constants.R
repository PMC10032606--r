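# Physical constants; repo-wide units are Angstrom, kcal/mol, ps, elementary
# charge, Kelvin.

.kB <- 0.0019872041            # Boltzmann constant, kcal/mol/K
.KE_COULOMB <- 332.0637        # Coulomb prefactor, kcal A / (mol e^2)

# (kg/s) -> kcal mol^-1 ps A^-2:  N_A / 4184 * 1e12 / 1e20
.GAMMA_CONV <- 6.02214076e23 / 4184 * 1e12 / 1e20

#' Thermal energy
#'
#' @param temperature temperature in K.
#' @return k_B T in kcal/mol.
#' @export
thermal_energy <- function(temperature) {
  stopifnot(temperature > 0)
  .kB * temperature
}
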