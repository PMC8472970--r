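# Desk-scale profile: CPU-sized training on synthetic phantoms.
seed: 1
network:
  base_width: 16
  upsample_mode: adaptive
  gating: true
train:
  epochs: 2
  batch_size: 32
  lr: 0.001
patches:
  size: 48
  per_image: 200
tiles:
  size: 48
  stride: 24
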