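{
  "variables": ["TDM", "FOM", "AI"],
  "beta0": 2.361,
  "beta": {
    "TDM": -0.016,
    "FOM": -0.172,
    "AI": -0.005
  },
  "se": {
    "(Intercept)": 0.353,
    "TDM": 0.004,
    "FOM": 0.073,
    "AI": 0.001
  },
  "loglik": null,
  "n": 200,
  "selection_path": null
}
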