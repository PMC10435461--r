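data_complex_2
_cell_length_a    7.5424(8)
_cell_length_b    29.800(3)
_cell_length_c    10.060(1)
_cell_angle_alpha 90
_cell_angle_beta  108.449(2)
_cell_angle_gamma 90
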