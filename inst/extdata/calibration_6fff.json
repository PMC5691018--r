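{
  "energy_label": "6FFF",
  "slope_m": 9.67e-05,
  "intercept_b": 1.0010,
  "slope_interval": [6.54e-05, 1.28e-04],
  "intercept_interval": [0.999, 1.003],
  "r_squared": 0.706,
  "fitted_support": [0, 120],
  "v_high": 300,
  "v_low": 150,
  "n_points": null,
  "seed": null
}
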