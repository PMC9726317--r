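{
  "intercept": -3.7207,
  "coef_age": -0.00696,
  "coef_atherosclerosis": -1.0531,
  "coef_ckd": -0.6161,
  "coef_antiplatelet": -0.8276,
  "coef_albumin": 0.8627,
  "cutoff_percent": 24.2
}
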