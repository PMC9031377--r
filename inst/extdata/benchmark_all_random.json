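{
  "seed": 1,
  "model": {
    "ftrue_ghz": 2.25,
    "amplitude_db": 18,
    "offset_db": 2,
    "sigma_left_ghz": 0.07,
    "sigma_right_ghz": 0.10,
    "fmin_ghz": 2,
    "fmax_ghz": 3
  },
  "monte_carlo": {
    "n_reps": 500,
    "ranges": {
      "alpha": [0.1, 0.9],
      "beta": [0.05, 0.45],
      "Nf": [100, 900],
      "Nt": [512, 4608],
      "N_hat_f": [512, 4608],
      "ftrue": [2.25e9, 2.75e9]
    },
    "algorithms": ["single_step", "iterative", "music"]
  }
}
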