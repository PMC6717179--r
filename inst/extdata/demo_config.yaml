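# Demonstration run: default 28-subject synthetic phantom cohort, full
# feature set, default effect model. `asirtex run --config` on this file
# (or run_full(load_config(...)) in R) reproduces the shipped example.
seed: 1
output_dir: asirtex_demo_out
input:
  type: synthetic
  n_subjects: 28
preprocessing:
  smoothing:
    kind: mean
    size: 3
  discretisation:
    n_bins: 32
    method: fixed_count
matrix:
  d: 1
families: [first_order, glcm, gldm, ngtdm, glrl, glzsm, fractal]
fractal:
  window: 8
  scales: [2, 4, 8]
  lacunarity_boxes: [2, 4, 8, 16]
  max_eps: 8
effect:
  log_features: [fractal_lacunarity]
  alpha: 0.05
  sigma_b_source: model
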