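# Example end-to-end run in phantom mode.
out_dir: plaquevae_out
seed: 1
log_level: info
calibration_fraction: 0.5
boundaries: calibrate
phantoms:
  lesionA:
    n_slices: 40
    class_sequence: [1,1,1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2,2,2,
                     3,3,3,3,3,3,3,3,3,3,4,4,4,4,4,4,4,4,4,4]
    seed: 11
  lesionB:
    n_slices: 20
    class_sequence: [1,1,1,1,1,2,2,2,2,2,3,3,3,3,3,4,4,4,4,4]
    seed: 12
vae:
  encoder_depths: [8, 16, 32, 64, 128]
  epochs: 30
  batch_size: 128
  learning_rate: 0.0005
  kl_weight: 0.0000813802083333  # 1 / (64*64*3): canonical unit-beta ELBO
  seed: 1
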