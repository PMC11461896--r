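# Shared fixtures: a standard 70 mL vial with 20 mL helium headspace, and
# the bottle geometry of the sediment incubations.

default_vial <- function(ppm = 0, temp = 20, pressure = 1) {
  headspace_vial(water_volume_ml = 50, headspace_volume_ml = 20,
                 equil_temp_c = temp, pressure_atm = pressure,
                 ch4_ppm = ppm)
}

river_assay <- function(initial = c(3, 3, 3), final = c(0.4, 0.4, 0.4)) {
  incubation_assay("river", initial, final, duration_h = 21,
                   water_volume_l = 0.070, sediment_volume_ml = 5,
                   bulk_density_g_ml = 0.96, bottle_diameter_mm = 41)
}

# single-site scenario used by the parameter-recovery simulations
recovery_scenario <- function(seed, noise_sd = 0.05, rate = -2.97) {
  synthetic_scenario(sites = "river", true_concentration_um = 3.0,
                     true_rate_um_l_d = rate, incubation_c0_um = 3.0,
                     duration_h = 21, noise_sd = noise_sd,
                     n_replicates = 3, seed = seed)
}
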