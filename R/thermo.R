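#' Thermodynamic conditions
#'
#' Bundle of the temperature and gas constant used everywhere a Boltzmann
#' factor or an RT*ln(10) conversion appears. All free energies in this
#' package are in kcal/mol, so the gas constant defaults to its value in
#' kcal/(mol K) at the conventional thermochemical temperature 298.15 K.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @param gas_constant Gas constant in kcal/(mol K). Must be positive.
#' @return An object of class \code{thermo_conditions}.
#' @examples
#' cond <- thermo_conditions()
#' rt_ln10(cond) # ~ 1.364 kcal/mol, the free energy of one log10 unit
#' @export
thermo_conditions <- function(temperature = 298.15, gas_constant = 1.98720425e-3) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive finite number (kelvin)")
  if (!is.numeric(gas_constant) || length(gas_constant) != 1L ||
      !is.finite(gas_constant) || gas_constant <= 0)
    stop("'gas_constant' must be a single positive finite number (kcal/(mol K))")
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("Thermodynamic conditions: T = %g K, R = %g kcal/(mol K), RT ln10 = %.5f kcal/mol\n",
              x$temperature, x$gas_constant, rt_ln10(x)))
  invisible(x)
}

#' Thermal energy RT and the log10 conversion factor RT ln(10)
#'
#' @param cond A \code{\link{thermo_conditions}} object.
#' @return \code{rt} returns R*T in kcal/mol; \code{rt_ln10} returns
#'   R*T*ln(10), the free-energy equivalent of one log10 unit (one log P
#'   unit or one pKa unit).
#' @export
rt <- function(cond = thermo_conditions()) {
  stopifnot(inherits(cond, "thermo_conditions"))
  cond$gas_constant * cond$temperature
}

#' @rdname rt
#' @export
rt_ln10 <- function(cond = thermo_conditions()) rt(cond) * log(10)

#' Aqueous proton free energy, decomposed
#'
#' The free energy of the solvated proton used to close the deprotonation
#' cycle: the gas-phase free energy of H+, the standard-state correction
#' from 1 atm to 1 M at 298 K, and the proton hydration free energy. The
#' defaults sum to -270.29 kcal/mol, the experimental value commonly used
#' with continuum-solvation pKa cycles.
#'
#' @param gas_phase_free_energy Gas-phase free energy of the proton, kcal/mol.
#' @param standard_state_correction 1 atm -> 1 M correction, kcal/mol.
#' @param hydration_free_energy Proton hydration free energy, kcal/mol.
#' @return An object of class \code{proton_parameters}.
#' @examples
#' proton_total(proton_parameters()) # -270.29
#' @export
proton_parameters <- function(gas_phase_free_energy = -6.28,
                              standard_state_correction = 1.89,
                              hydration_free_energy = -265.9) {
  vals <- c(gas_phase_free_energy, standard_state_correction, hydration_free_energy)
  if (!is.numeric(vals) || length(vals) != 3L || !all(is.finite(vals)))
    stop("proton parameters must be three finite numbers (kcal/mol)")
  structure(list(gas_phase_free_energy = gas_phase_free_energy,
                 standard_state_correction = standard_state_correction,
                 hydration_free_energy = hydration_free_energy),
            class = "proton_parameters")
}

#' Total aqueous proton free energy
#'
#' @param proton A \code{\link{proton_parameters}} object.
#' @return Sum of the three components, kcal/mol (-270.29 with defaults).
#' @export
proton_total <- function(proton = proton_parameters()) {
  stopifnot(inherits(proton, "proton_parameters"))
  proton$gas_phase_free_energy + proton$standard_state_correction +
    proton$hydration_free_energy
}

#' @export
print.proton_parameters <- function(x, ...) {
  cat(sprintf("Aqueous proton free energy: %.2f + %.2f + %.2f = %.2f kcal/mol\n",
              x$gas_phase_free_energy, x$standard_state_correction,
              x$hydration_free_energy, proton_total(x)))
  invisible(x)
}

.check_finite <- function(x, what) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop(sprintf("'%s' must be finite numeric (kcal/mol)", what))
  invisible(x)
}

#' Water-to-octanol transfer free energy
#'
#' The transfer free energy of a neutral solute from water to n-octanol is
#' the difference of its two solvation free energies:
#' ddG(w->o) = dG_solv(octanol) - dG_hyd(water). Negative values mean the
#' compound is more stable in octanol (lipophilic).
#'
#' @param dg_solv_octanol Solvation free energy in n-octanol, kcal/mol.
#' @param dg_hyd_water Hydration free energy, kcal/mol.
#' @return Transfer free energy in kcal/mol. Vectorized.
#' @seealso \code{\link{logp_from_transfer}}
#' @export
transfer_free_energy <- function(dg_solv_octanol, dg_hyd_water) {
  .check_finite(dg_solv_octanol, "dg_solv_octanol")
  .check_finite(dg_hyd_water, "dg_hyd_water")
  dg_solv_octanol - dg_hyd_water
}

#' log P from the transfer free energy
#'
#' log P = -ddG(w->o) / (RT ln10): a compound 1.364 kcal/mol more stable in
#' octanol than in water (at 298.15 K) has log P = +1.
#'
#' @param ddg_transfer Water-to-octanol transfer free energy, kcal/mol.
#' @param cond \code{\link{thermo_conditions}}.
#' @return log10 of the octanol/water partition coefficient. Vectorized.
#' @export
logp_from_transfer <- function(ddg_transfer, cond = thermo_conditions()) {
  .check_finite(ddg_transfer, "ddg_transfer")
  -ddg_transfer / rt_ln10(cond)
}

#' pKa from the aqueous deprotonation cycle
#'
#' For the equilibrium HX -> X- + H+ in water,
#' dG_aq = G_aq(X-) + G_aq(H+) - G_aq(HX) and pKa = dG_aq / (RT ln10),
#' with G_aq(H+) taken from \code{\link{proton_parameters}}.
#'
#' @param g_aq_acid Aqueous free energy of the protonated species, kcal/mol.
#' @param g_aq_base Aqueous free energy of the deprotonated species, kcal/mol.
#' @param proton \code{\link{proton_parameters}}.
#' @param cond \code{\link{thermo_conditions}}.
#' @return pKa (dimensionless). Vectorized over the two free energies.
#' @export
pka_from_deprotonation <- function(g_aq_acid, g_aq_base,
                                   proton = proton_parameters(),
                                   cond = thermo_conditions()) {
  .check_finite(g_aq_acid, "g_aq_acid")
  .check_finite(g_aq_base, "g_aq_base")
  stopifnot(inherits(proton, "proton_parameters"))
  dg_aq <- g_aq_base + proton_total(proton) - g_aq_acid
  dg_aq / rt_ln10(cond)
}
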