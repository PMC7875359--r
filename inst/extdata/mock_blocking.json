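{
  "params": {
    "block": {"enabled": true, "I_block": 0.45, "t_block": 400, "v_eq": -42}
  },
  "morphology": {}
}
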