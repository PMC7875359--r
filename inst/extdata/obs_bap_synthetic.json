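{
  "AP1_amp_50": {"mean": 75.0, "std": 15.0},
  "AP1_amp_150": {"mean": 60.0, "std": 15.0},
  "AP1_amp_250": {"mean": 45.0, "std": 15.0},
  "AP1_amp_350_strong": {"mean": 48.0, "std": 8.0},
  "AP1_amp_350_weak": {"mean": 12.0, "std": 5.0},
  "APlast_amp_50": {"mean": 60.0, "std": 15.0},
  "APlast_amp_150": {"mean": 45.0, "std": 15.0},
  "APlast_amp_250": {"mean": 35.0, "std": 15.0},
  "APlast_amp_350": {"mean": 30.0, "std": 15.0}
}
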