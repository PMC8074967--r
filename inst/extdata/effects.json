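{
  "environment": "csgh",
  "alpha1": 0.3,
  "sigma2_h": 0.05,
  "selection": "csgh_prob",
  "qrp": "none",
  "n_target": 40,
  "seed": 42
}
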