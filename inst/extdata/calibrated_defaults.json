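{
  "n_cells": 100,
  "coupling_radius": 3,
  "hill_exponent": 4,
  "alpha_B": 1.9,
  "alpha_V": 1.83,
  "beta_B": 1,
  "beta_V": 1,
  "delta_F": 1,
  "delta_B": 1,
  "delta_V": 1,
  "K_BB": 0.41,
  "K_VB": 1.58,
  "K_VV": 0.95,
  "K_lo": 2.9,
  "K_hi": 6.69,
  "c_BV": 0.69,
  "sigma_init": 0.02,
  "sigma_dyn": 0
}
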