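## Physical constants (CODATA 2018) and unit conversions.  Every conversion in
## the package goes through these helpers so that the kT convention is set in
## exactly one place.

.kB_J_per_K <- 1.380649e-23      # Boltzmann constant, J/K
.N_avogadro <- 6.02214076e23     # 1/mol
.e_coulomb <- 1.602176634e-19    # elementary charge, C
.R_kcal_per_mol_K <- 1.987204259e-3  # gas constant, kcal/mol/K
.angstrom_m <- 1e-10

#' Physical constants used throughout the package
#'
#' Returns the constants table: Boltzmann constant, Avogadro number,
#' elementary charge and the thermal energy at the requested temperature in
#' several unit systems. All free energies in the package are stored in kT
#' units at a stated temperature (default 310 K), so that the Boltzmann
#' factor `exp(-W/kT)` is simply `exp(-w)`.
#'
#' @param temperature_K absolute temperature in kelvin.
#' @return Named list with elements `kB_J_per_K`, `N_avogadro`, `e_C`,
#'   `kT_J` (thermal energy in joules), `kT_kcal_mol` (kcal/mol),
#'   `kT_mV` (thermal voltage in millivolts) and `kcal_mol_per_kT`.
#' @examples
#' physical_constants(310)$kT_kcal_mol  # ~0.616 kcal/mol
#' @export
physical_constants <- function(temperature_K = 310) {
  list(
    kB_J_per_K = .kB_J_per_K,
    N_avogadro = .N_avogadro,
    e_C = .e_coulomb,
    kT_J = .kB_J_per_K * temperature_K,
    kT_kcal_mol = .R_kcal_per_mol_K * temperature_K,
    kT_mV = 1000 * .kB_J_per_K * temperature_K / .e_coulomb,
    kcal_mol_per_kT = .R_kcal_per_mol_K * temperature_K
  )
}

kT_joules <- function(temperature_K = 310) .kB_J_per_K * temperature_K

kT_kcal_mol <- function(temperature_K = 310) .R_kcal_per_mol_K * temperature_K

## thermal voltage in mV (kT/e)
kT_millivolts <- function(temperature_K = 310) {
  1000 * kT_joules(temperature_K) / .e_coulomb
}

## harmonic force constant kcal/mol/A^2 -> kT/A^2
force_constant_kT <- function(k_kcal_mol_A2, temperature_K = 310) {
  k_kcal_mol_A2 / kT_kcal_mol(temperature_K)
}
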