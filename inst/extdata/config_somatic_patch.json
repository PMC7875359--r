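{
  "amplitudes": [-0.25, -0.2, -0.15, -0.1, -0.05, 0.15, 0.2, 0.25],
  "delay": 500,
  "duration": 1000,
  "tstop": 1700
}
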