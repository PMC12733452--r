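# Example desk-scale pipeline configuration for the sonoseg CLI.
out_dir: sonoseg_out
image_size: 64
phantom:
  n_patients: 8
  slices_per_patient: 4
  image_size: 64
model:
  architecture: unet
  base_width: 16
  depth: 4
train_cfg:
  batch_size: 16
  learning_rate: 0.001
  max_epochs: 4
  seed: 1
split_fractions: [0.5, 0.25, 0.25]
sonification:
  duration_per_region: 1.5
  tempo: 90
seed: 1
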