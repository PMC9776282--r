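# Reduced-width model on 64-pixel inputs for CPU-scale training.
model:
  input_size: 64
  in_channels: 3
  patch_size: 8
  r: 1
  stem_channels: 16
  stages:
    - {l: 1, d0: 32, heads: 2}
  pixel_shuffle_factor: 4
  condense_channels: 8
  head_hidden: 8
  d_class: 8
train:
  lr: 0.001
  lr_decay: 0.99
  batch_size: 20
  epochs: 60
  val_split: 0.0
vocab: private8
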