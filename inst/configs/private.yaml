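# Reference architecture, 8-class stroke-rehabilitation vocabulary.
model:
  input_size: 128
  in_channels: 3
  patch_size: 8
  r: 1
  stem_channels: 64
  stages:
    - {l: 2, d0: 192, heads: 8}
    - {l: 4, d0: 576, heads: 4}
  pixel_shuffle_factor: 12
  condense_channels: 4820
  head_hidden: 124
  d_class: 8
train:
  lr: 0.0003
  lr_decay: 0.99
  batch_size: 120
  epochs: 200
vocab: private8
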