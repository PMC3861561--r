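# x40 field of the reference acquisition system (2560 x 1920 px)
width_um: 310.3
height_um: 232.72
um_per_px: 0.12121
objective_label: x40
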