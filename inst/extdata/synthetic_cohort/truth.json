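{
  "model_id": "example_axillary_logistic",
  "seed": 2026,
  "a_true": 0,
  "b_true": 1,
  "horizon": {},
  "n_requested": 80,
  "n": 80,
  "prevalence": 0.2125,
  "masked": {
    "hilum": 9,
    "tumor_size": 7
  },
  "n_censored_dropped": 0
}
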