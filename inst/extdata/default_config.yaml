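n_subjects: 9
sampling_rate: 300.0
mesh:
  n_vertices_per_hemisphere: 64
gain:
  n_sensors: 32
  smoothness: 10.0
  falloff: 2.0
  subject_gain_sd: 0.05
paradigm:
  attend_block_s: 60.0
  passive_block_s: 30.0
  inter_pair_s: 3.4
  sound_duration_s: 0.3
  gap_s: 0.25
  first_pair_offset_s: 1.0
  post_margin_s: 1.75
  n_block_cycles: 2
truth:
  planted_rois:
  - pericalcarine
  - lingual
  power_ratio: 2.0
  effect_band:
  - 7.0
  - 13.0
  evoked_amplitude: 2.0
  alpha_snr: 4.0
  artifact_frac: 0.08
  subject_effect_sd: 0.1
noise:
  sigma: 1.0
  rho: 0.3
inverse:
  snr: 3.0
  depth_exponent: 0.8
  loose_factor: 0.6
  loading_fraction: 0.05
spectral:
  freq_range:
  - 4.0
  - 80.0
  tfr_freqs:
  - 5.0
  - 7.0
  - 9.0
  - 11.0
  - 13.0
  - 15.0
  - 17.0
  - 19.0
  - 21.0
  - 23.0
  - 25.0
  - 27.0
  - 29.0
  - 31.0
  - 33.0
  - 35.0
  - 37.0
  - 39.0
  - 41.0
  - 43.0
  - 45.0
  - 47.0
  - 49.0
  - 51.0
  - 53.0
  - 55.0
  - 57.0
  - 59.0
  - 61.0
  - 63.0
  - 65.0
  - 67.0
  - 69.0
  - 71.0
  - 73.0
  - 75.0
  - 77.0
  - 79.0
  n_cycles: 3.0
  stride_s: 0.05
  eog_threshold_uv: 100.0
stats:
  alpha: 0.05
  n_randomizations: 1500
  cluster_bands:
  - theta
  - alpha
  - beta
  - gamma
  tfr_rois: ~
  run_tfr_stats: yes
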