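# Desk-scale demonstration run: a full simulate -> split -> train ->
# extract -> evaluate pipeline sized for a single CPU.
seed: 20260927
out_dir: desk_run
cohort:
  n_patients: 17
  n_controls: 17
  age_range: [18, 65]
sim:
  grid_shape: [24, 28, 24]
  n_timepoints: 40
  signature_amplitude: 5
  group_amplitude: 4
  age_amplitude: 2
  noise_sd: 1
  smoothing_sigma_vox: 1.5
split:
  train1: [6, 6]
  train2: [4, 4]
  test: [7, 7]
encoder:
  n_blocks: 2
  base_channels: 8
train:
  lr_schedule:
    - [0.0001, 1500]
    - [0.00001, 500]
  batch_size: 4
baselines:
  pca_m: 3
  n_rois: 12
eval:
  lambda_diagnosis: 0.1
  lambda_age: 1
  precision_k: 40
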