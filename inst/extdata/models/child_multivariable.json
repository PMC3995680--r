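{
  "nonlocomotive": {
    "intercept": -0.537,
    "coef_sa": 0.013,
    "coef_age": 0.170,
    "coef_sex": 0.076,
    "r2": 0.816,
    "rmse": 0.596
  },
  "locomotive": {
    "intercept": -0.925,
    "coef_sa": 0.005,
    "coef_weight": 0.032,
    "coef_age": 0.085,
    "coef_sex": 0.092,
    "r2": 0.925,
    "rmse": 0.508
  },
  "classifier": {
    "threshold": 1.12,
    "movement_floor_mg": 3,
    "bout_rule": "majority_vote"
  },
  "provenance": "child_multivariable"
}
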