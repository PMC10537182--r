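# Example wavestate pipeline configuration (all fields optional; anything
# omitted falls back to the package defaults shown by
# default_pipeline_config()).

simulate:
  n_subjects: 1
  sessions_per_subject: 1
  minutes_per_state: 2       # 4 segments per state per session
  fs: 128
  channels: 14
  profiles: default          # default | null | explicit per-state lists
  master_seed: 11

window_seconds: 30

transforms:
  mdwt: {wavelet_name: db2, levels: 4}
  tqwt: {q: 2, R: 5, B: 7}
  fawt: {B: 6, p: 3, q: 5, r: 2, s: 3}

subbands:
  mode: fixed                # fixed | auto (per-subband CV screen)
  mdwt: 1
  tqwt: 1
  fawt: 7

ranking:
  bins: 10
  k: 4

classifier:
  budget: 6
  cv: kfold_10               # holdout_80_20 | kfold_5 | kfold_10
  imv_rounds: 5
  paper_eq11: false

seed: 1
out_dir: wavestate_out
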