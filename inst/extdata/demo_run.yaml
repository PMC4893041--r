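# demonstration run: 4 simulated patients, pre/post, two readers
seed: 1
out_dir: runs/demo
stages: [phantom, quantify, score, report]
phantom:
  n_patients: 4
  n_joints: 6
  matrix_size: [64, 64]
  background_rate: 10000
  psf_sigma_px: 1
  tb_mean: 1.05
  tb_sd: 0.25
  effect_mean: -0.25
  effect_sd: 0.1
scoring:
  n_readers: 2
  reader_sd: 0.05
  positivity_threshold: 1
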