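# Example run configuration (desk scale). Unset keys keep package defaults.
spatial3d:
  d: 64
  dropout: 0.1
  epsilon: 1.0e-8
topo2d:
  n_layers: 4
  heads: 2
  head_dim: 32
  share_parameters: true
  pool_ratios: [0.5, 0.25]
contrastive:
  scales: [1, 2, 4]
  gamma0: 0.1
  T: 500
model:
  use_3d: true
  use_dfe: true
  use_contrast: true
  score_mode: fused
train:
  epochs: 50
  batch_size: 64
  lr: 0.001
  weight_decay: 0.001
  seed: 1
  eval_every: 5
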