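{
  "mean_threshold": 3.9, "std_threshold": 1.0,
  "mean_prox_threshold": 3.9, "std_prox_threshold": 1.5,
  "mean_dist_threshold": 3.8, "std_dist_threshold": 1.6,
  "mean_nonlin_at_th": 144.0, "std_nonlin_at_th": 43.0,
  "mean_suprath_nonlin": 117.0, "std_suprath_nonlin": 25.0,
  "mean_peak_deriv": 2.6, "std_peak_deriv": 1.2,
  "mean_peak_amp": 7.1, "std_peak_amp": 2.0,
  "mean_time_to_peak": 5.0, "std_time_to_peak": 3.0,
  "mean_async_nonlin": 104.0, "std_async_nonlin": 25.0
}
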