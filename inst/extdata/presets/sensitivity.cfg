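# NEMA point-source sensitivity scan: 89.9 kBq Na-22 point source stepped
# along X at the midplane, heads separated by 60 mm.
protocol = sensitivity
separation = 60
step_mm = 2
span_mm = 224
n_decays_per_position = 1e5
seed = 1
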