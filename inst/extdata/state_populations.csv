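system,S1,S2,S3,S4,S5,S6
apo,4.9,1.9,1.2,16.7,10,NA
bound_1,5.7,6.3,9.5,7.3,0.4,8.3
bound_2,11.1,0.5,4.4,3.6,11.5,7.0
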