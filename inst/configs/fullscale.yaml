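# Full-scale profile matching the reference training protocol
# (GPU-scale; not intended for single-CPU runs).
seed: 1
network:
  base_width: 32
  upsample_mode: adaptive
  gating: true
train:
  epochs: 200
  batch_size: 256
  lr: 0.001
  beta1: 0.9
  step_decay: 0.01
  weight_decay: 0.0005
patches:
  size: 48
  per_image: 10480
tiles:
  size: 48
  stride: 24
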