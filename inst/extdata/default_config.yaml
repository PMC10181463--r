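# Default pipeline configuration.  Every key shown here is optional;
# omitted keys take these values and unknown keys are rejected.

io:
  dialect: csv          # csv | edf
  trigger_label: TRIGGER

preprocess:
  low_hz: 0.5           # Butterworth band-pass edges (Hz)
  high_hz: 59
  order: 3
  application: zero_phase   # zero_phase | causal
  trim_s: 5             # seconds discarded at each epoch edge
  win_len_s: 2          # analysis window length (s)
  overlap_frac: 0.5     # fractional window overlap
  threshold: 0.5        # trigger threshold (fraction of dynamic range)
  min_width_s: 0.25     # minimum trigger pulse width (s)

features:
  orders: [1,2,3,4,5,6,7,8,9,10]
  kind: central         # central | raw | standardized
  normalize: recording  # recording | none

selection:
  n_trees: 50           # forest size during greedy selection
  max_k: 10
  tol: 0.001

grid:
  n_trees: [50, 100, 200]
  max_depth: [none, 8, 16]
  mtry_rule: [sqrt, log2]

evaluation:
  framework: 1
  seed: 1

simulation:
  n_subjects: 9
  n_recordings: 2
  montage: vamp16       # vamp16 | fp1
  fs: 512
  subject_sd: 0.8
  session_sd: 0.25
  effect_scale: 1       # 0 removes all class information
  seed: 1
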