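{
  "compound": { "name": "mCPP", "molecular_weight": 196.68, "log_p": 2.06, "p_ka": 8.87 },
  "scenario": { "c_w_um": 5, "t_uptake_h": 8, "t_depuration_h": 48 },
  "body": { "larva_weight_ug": 360, "eye_mass_fraction": 0.10 },
  "passive": { "lipid_fraction": 0.05, "body_weight_kg": 3.6e-7, "water_temperature_c": 28 },
  "noise": { "kind": "multiplicative-lognormal", "cv": 0.06, "seed": 1 }
}
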