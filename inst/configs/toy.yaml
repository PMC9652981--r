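# Scaled-down profile for single-CPU phantom experiments.
seed: 7
network:
  variant: transresseunet25d
  stage_channels: [8, 16, 32, 64, 128]
  patch: [16, 64, 64]
transformer:
  M: 2
  H: 4
  h: 256
  C3: 128
train:
  batch_size: 4
  epochs: 15
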