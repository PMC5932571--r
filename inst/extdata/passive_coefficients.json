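{
  "framework_version": "gill-uptake-kinetic-1.0",
  "comment": "Fish gill-uptake bioaccumulation coefficients (Arnot & Gobas kinetic formulation). Rates are computed per day and converted to per hour.",
  "uptake_efficiency": { "a": 1.85, "b": 155.0 },
  "ventilation": { "coefficient_l_per_day": 1400.0, "weight_exponent": 0.65 },
  "oxygen_saturation": { "slope_mg_per_l_per_c": -0.24, "intercept_mg_per_l": 14.04, "saturation_fraction": 0.9 }
}
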