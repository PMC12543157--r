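{
  "n_patients": 50000,
  "seed": 20140101,
  "baseline_death_prob": 0.02,
  "transfer_prob": 0.011,
  "group_prevalences": {"8a": 0.015},
  "death_relative_risks": {"8a": 10},
  "min_lift": 1.1,
  "min_count": 4,
  "out_dir": "results/demo"
}
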