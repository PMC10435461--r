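data_complex_1
_cell_length_a    7.5570(2)
_cell_length_b    29.5198(6)
_cell_length_c    10.2393(2)
_cell_angle_alpha 90
_cell_angle_beta  106.398(1)
_cell_angle_gamma 90
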