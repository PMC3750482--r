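{
  "comment": "Sparse outline classifier transcribed for Kc167-type (400x400) actin images; applies to raw feature values, probability = 1/(1+exp(+eta)).",
  "intercept": 1.120,
  "coefficients": {
    "ENT_5x5": -0.0165,
    "DOE_7x7": -0.1790,
    "IMOC2_7x7": -0.360,
    "IMOC2_9x9": -1.54,
    "ASM_9x9": 0.1908
  },
  "lambda": null,
  "threshold": 0.5,
  "link_sign": 1,
  "standardization": {
    "mean": {"ENT_5x5": 0, "DOE_7x7": 0, "IMOC2_7x7": 0, "IMOC2_9x9": 0, "ASM_9x9": 0},
    "scale": {"ENT_5x5": 1, "DOE_7x7": 1, "IMOC2_7x7": 1, "IMOC2_9x9": 1, "ASM_9x9": 1}
  }
}
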