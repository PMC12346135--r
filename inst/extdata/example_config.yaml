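# Scaled-down experiment configuration (see read_config_yaml)
model:
  num_classes: 2
  base_channels: 8
train:
  batch_size: 2
  max_iterations: 300
  crop_size: 64
  seed: 5
  val_interval: 50
loss:
  lambda_dice: 0.5
augment:
  rotation_deg: 25
  hflip_prob: 0.5
  vflip_prob: 0.5
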