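electrostatic,polarization,dispersion,repulsion
-14.36,-4.57,-68.31,31.26
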