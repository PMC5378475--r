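{
  "version": 1,
  "seed": 20260930,
  "stages": {
    "survival": {
      "cohorts": [
        {"group": "solitary", "n": 40, "target_mean": 12.0, "aging_rate": 0.25},
        {"group": "grouped8", "n": 80, "target_mean": 7.7, "aging_rate": 0.25}
      ]
    },
    "demography": {
      "r": [1.0, 0.768],
      "m0": 0.5,
      "generations": 20,
      "threshold": 0.01,
      "days_per_generation": 3
    },
    "chemotaxis": {
      "method": "t",
      "groups": [
        {"group": "supernatant", "n_plates": 12, "n_worms": 30,
         "p_super": 0.55, "p_ctrl": 0.15, "p_origin": 0.10},
        {"group": "mock", "n_plates": 12, "n_worms": 30,
         "p_super": 0.35, "p_ctrl": 0.35, "p_origin": 0.10}
      ]
    }
  }
}
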