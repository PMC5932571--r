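# Shared fixtures: the study compound, exposure design and reported rates.

mcpp <- compound("mCPP", molecular_weight = 196.68, log_p = 2.06, p_ka = 8.87)

# 5 uM (0.98 mg/L) for 8 h uptake, 48 h depuration
scenario_8_48 <- exposure_scenario(c_w = 0.98, t_uptake = 8, t_depuration = 48)

params_whole <- one_compartment_params(k_in = 112.9, k_out = 0.25)
params_eye_rest <- multi_compartment_params(k_in_eyes = 325, k_out_eyes = 0.05,
                                            k_in_rest = 143.2, k_out_rest = 0.8)
body_default <- body_composition(larva_weight_ug = 360, eye_mass_fraction = 0.10)

# Piecewise biexponential depuration series: half-life `t_half_1` up to
# `t_break`, then `t_half_2`, evaluated at `times` since depuration start.
biexponential_depuration <- function(times, c0 = 308, t_half_1 = 4.5,
                                     t_half_2 = 28.5, t_break = 6) {
  k1 <- log(2) / t_half_1
  k2 <- log(2) / t_half_2
  c_break <- c0 * exp(-k1 * t_break)
  ifelse(times <= t_break,
         c0 * exp(-k1 * times),
         c_break * exp(-k2 * (times - t_break)))
}

depuration_df <- function(times, conc) {
  data.frame(time_h = times, conc_mg_per_kg = conc)
}
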