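pair,S1,S2,S3,S4,S5
core|bb_loop,17.2,17.4,16.1,18.7,20.4
bb_loop|beta,19.7,19.4,20,19.2,20.2
core|beta,24.5,24.2,24.6,26,26.7
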