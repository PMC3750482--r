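{
  "comment": "Sparse outline classifier transcribed for HeLa-type (1040x1392, 12-bit) actin images; applies to raw feature values, probability = 1/(1+exp(+eta)).",
  "intercept": 0.2415,
  "coefficients": {
    "VAR_3x3": -44.998,
    "MIN_7x7": 0.010,
    "GABOR_f0.25_th0_5x5": -0.006,
    "GABOR_f0.25_th0.75pi_5x5": -0.009,
    "ASM_5x5": 0.068,
    "IMOC2_7x7": -0.207,
    "IMOC2_9x9": -0.544
  },
  "lambda": null,
  "threshold": 0.5,
  "link_sign": 1,
  "standardization": {
    "mean": {"VAR_3x3": 0, "MIN_7x7": 0, "GABOR_f0.25_th0_5x5": 0, "GABOR_f0.25_th0.75pi_5x5": 0, "ASM_5x5": 0, "IMOC2_7x7": 0, "IMOC2_9x9": 0},
    "scale": {"VAR_3x3": 1, "MIN_7x7": 1, "GABOR_f0.25_th0_5x5": 1, "GABOR_f0.25_th0.75pi_5x5": 1, "ASM_5x5": 1, "IMOC2_7x7": 1, "IMOC2_9x9": 1}
  }
}
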