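# Independent brute-force oracles: direct exponential summation, no shift.
# Valid for moderate energies (|G| <= ~15 kcal/mol at 298 K).
oracle_lse <- function(g, cond = thermo_conditions()) {
  kt <- cond$gas_constant * cond$temperature
  -kt * log(sum(exp(-g / kt)))
}

oracle_weights <- function(g, cond = thermo_conditions()) {
  kt <- cond$gas_constant * cond$temperature
  exp(-g / kt) / sum(exp(-g / kt))
}

# Macroscopic pKa by direct exponentials over all conformers of all
# microstates in each charge state.
oracle_macro_pka <- function(acid_energies, base_energies,
                             proton = proton_parameters(),
                             cond = thermo_conditions()) {
  dg <- oracle_lse(unlist(base_energies), cond) + proton_total(proton) -
    oracle_lse(unlist(acid_energies), cond)
  dg / (cond$gas_constant * cond$temperature * log(10))
}

# One-compound conformer table with explicit component values.
make_conformers <- function(compound_id, gas, th_w, th_o, ds_w, ds_o,
                            ids = sprintf("c%02d", seq_along(gas))) {
  conformer_table(data.frame(
    compound_id = compound_id, conformer_id = ids,
    gas_energy_kcal = gas,
    thermal_water_kcal = th_w, thermal_octanol_kcal = th_o,
    dgsolv_water_kcal = ds_w, dgsolv_octanol_kcal = ds_o,
    stringsAsFactors = FALSE))
}
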