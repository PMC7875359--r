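{
  "mean_attenuation_soma/dend_100_um": 0.42,
  "std_attenuation_soma/dend_100_um": 0.1,
  "mean_attenuation_soma/dend_200_um": 0.28,
  "std_attenuation_soma/dend_200_um": 0.07,
  "mean_attenuation_soma/dend_300_um": 0.15,
  "std_attenuation_soma/dend_300_um": 0.05
}
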