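grid_shape: [64, 64]
n_frames: 60
frame_rate: 440
bubble_rate: 0.1
psf_sigma: 1.2
clutter_amplitude: 15
clutter_rank: 2
noise_sigma: 0.2
seed: 7
vessels:
  - centerline: [[20, 0], [20, 63]]
    radius: 1.5
    flow_speed: 1.0
  - centerline: [[45, 0], [45, 63]]
    radius: 1.5
    flow_speed: 1.3
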