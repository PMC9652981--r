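# Reference protocol (full scale). Requires clinical-scale training data and
# GPU-class compute; provided for completeness, not as a runnable test.
seed: 1
network:
  variant: transresseunet25d
  stage_channels: [16, 32, 64, 128, 256]
  patch: [32, 256, 256]
transformer:
  M: 4
  H: 8
  h: 4096
  C3: 512
train:
  batch_size: 4
  lr0: 0.001
  weight_decay: 0.0001
  poly_power: 0.9
  epochs: 500
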