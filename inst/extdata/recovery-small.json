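{
  "experiment": "recovery",
  "snr_levels": [10, 20, 50],
  "n_total_levels": [45, 90, 270],
  "bvalues": [1000, 2000, 3000],
  "n_trials": 50
}
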