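{
  "comment": "Demonstration regime: non-cooperative binding with Kd = 5.1 uM, tetrameric pores (m = 4), kill threshold calibrated so the killing IC50 is 10.2 uM, log-normal threshold spread 0.6.",
  "kd": 5.1,
  "target_ic50": 10.2,
  "m": 4,
  "site_density": 1.0,
  "k_olig": 1.0,
  "theta_sigma": 0.6
}
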