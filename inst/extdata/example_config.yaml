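# Example synthetic-mode pipeline configuration.
mode: synthetic
out_dir: artikin-demo
seed: 7
design:
  n_subjects_per_group:
    FS: 6
    AWS: 6
  n_repetitions: 5
  n_frames_mean: 60
  duration_jitter_sd: 4
render: false
prep:
  min_reps: 1
  max_reps: 10
  drop_first: 0
fosr:
  enabled: true
  sites: [LA, TTR]
  test: wald
cluster:
  linkage: ward
  k_range: [2, 3, 4, 5, 6]
  mode: repetition
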