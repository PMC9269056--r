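# NU-4 rat scatter phantom count-rate series: 51 MBq F-18 line source in the
# HDPE cylinder, frames repeated until 10 half-lives have elapsed.
# Frame spacing is coarsened to 60 min and per-frame decays capped so the
# series stays desk-scale; rates are unbiased by the cap.
protocol = countrate
separation = 60
frame_interval_min = 60
frame_duration_s = 30
stop_half_lives = 10
max_decays_per_frame = 3e5
angle_allowance_mm = 110
peak_concentration_kbq_ml = 10.5
seed = 1
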