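sr_factor: 8
vd: true
svd: {n_tissue_components: 2, noise_threshold: 1}
localization: {min_peak_intensity: 1.5}
tracker: {gate_radius: 5}
motion: {block_size: 16, search_range: 2}
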