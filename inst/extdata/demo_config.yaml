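# Demo profile: full six-algorithm benchmark on a synthetic nocturnal cohort.
seed: 1
cohort:
  n_patients: 160
  shapes: [stable_target, stable_elevated, downward_trend, upward_trend,
           hypo_dip, hypo_low_stable]
  noise_phi: 0.8
  noise_sigma: 0.3
  offset_sigma: 0.5
  gap_rate_single: 0.02
  gap_rate_long: 0.05
preprocess:
  nh_threshold: 3.9
  nh_min_run: 3
  split: [0.7, 0.1, 0.2]
cluster:
  k_range: [2, 8]
  stability_reps: 0
forecast:
  algorithms: [mtsc, wmtsc, holt, gbt_global, rf_cluster, gbt_cluster]
  horizons: [15, 30]
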