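{
  "AP_begin_voltage": {
    "0.15": {"mean": -51.13, "std": 0.97},
    "0.2": {"mean": -50.14, "std": 1.97},
    "0.25": {"mean": -49.36, "std": 2.02}
  },
  "AP_amplitude_from_voltagebase": {
    "0.15": {"mean": 98.36, "std": 5.82},
    "0.2": {"mean": 96.83, "std": 5.66},
    "0.25": {"mean": 95.99, "std": 5.22}
  },
  "AP_duration_half_width": {
    "0.15": {"mean": 1.23, "std": 0.096},
    "0.2": {"mean": 1.25, "std": 0.11},
    "0.25": {"mean": 1.32, "std": 0.086}
  },
  "sag_ratio2": {
    "-0.05": {"mean": 0.79, "std": 0.023},
    "-0.1": {"mean": 0.81, "std": 0.03},
    "-0.15": {"mean": 0.81, "std": 0.027},
    "-0.2": {"mean": 0.81, "std": 0.03},
    "-0.25": {"mean": 0.8, "std": 0.03}
  }
}
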