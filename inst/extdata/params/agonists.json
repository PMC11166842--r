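{
  "CP": {
    "citation": "reference agonist; pKd/k_int estimated, log10_eps from operational-model fit",
    "overrides": {}
  },
  "WIN": {
    "citation": "pKd from radioligand binding literature; k_int and log10_eps from operational-model fits; kon3 fixed to the CP value",
    "overrides": {
      "pKd": 7.7,
      "k_int": 0.28,
      "log10_eps": 2.63,
      "kon3": 0.53
    }
  },
  "THC": {
    "citation": "pKd from binding literature; k_int and log10_eps from operational-model fits; kon3 fixed to the CP value",
    "overrides": {
      "pKd": 8.0,
      "k_int": 0.029,
      "log10_eps": 0.85,
      "kon3": 0.53
    }
  },
  "THC_calibrated": {
    "citation": "as THC but kon3 decreased ten-fold by calibration against cAMP traces (probe dependence)",
    "overrides": {
      "pKd": 8.0,
      "k_int": 0.029,
      "log10_eps": 0.85,
      "kon3": 0.05
    }
  }
}
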