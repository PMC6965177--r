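{
  "command": "expected-corr",
  "seed": 1,
  "signal": { "mu_x": 5, "mu_y": 7, "var_x": 1, "var_y": 1, "rho0": 0.6 },
  "error": {
    "model_kind": "realistic",
    "var_au": 0.3,
    "var_ac": 0.2,
    "var_mu": 0.02,
    "var_mc": 0.05
  }
}
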