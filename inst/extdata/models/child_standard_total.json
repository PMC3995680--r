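{
  "nonlocomotive": {
    "intercept": 1.220,
    "coef_sa": 0.013,
    "r2": 0.772,
    "rmse": 0.664
  },
  "locomotive": {
    "intercept": 0.944,
    "coef_sa": 0.005,
    "r2": 0.880,
    "rmse": 0.639
  },
  "classifier": {
    "threshold": 1.12,
    "movement_floor_mg": 3,
    "bout_rule": "majority_vote"
  },
  "provenance": "child_standard_total"
}
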