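{
  "mean_Ith": 0.45,
  "Ith_std": 0.07,
  "mean_Veq": -42.0,
  "Veq_std": 3.0
}
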