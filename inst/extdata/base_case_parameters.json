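{
  "cohort_size": 100,
  "prevalence": {"angiodysplasia": 0.50, "ulcer": 0.30, "tumor": 0.20},
  "vce_sens": {"angiodysplasia": 0.90, "ulcer": 0.85, "tumor": 0.55},
  "vce_spec": {"angiodysplasia": 0.90, "ulcer": 0.99, "tumor": 0.90},
  "cte_sens": {"angiodysplasia": 0.20, "ulcer": 0.30, "tumor": 0.90},
  "cte_spec": {"angiodysplasia": 0.99, "ulcer": 0.99, "tumor": 0.99},
  "triage_sens": 0.735,
  "triage_spec": 0.790,
  "costs": {
    "USD": {"vce": 1247, "cte": 518},
    "THB": {"vce": 42000, "cte": 15400}
  }
}
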