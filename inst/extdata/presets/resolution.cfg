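# Centered point-source spatial-resolution protocol: 80 mm separation,
# >= 1e5 prompts, 0.2 mm pixels, MLEM 15 iterations plus back-projection.
protocol = resolution
separation = 80
n_prompts = 1e5
pixel_size_mm = 0.2
n_iterations = 15
extent_xy_mm = 25.6
seed = 1
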