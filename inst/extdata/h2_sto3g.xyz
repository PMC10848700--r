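2
h2_sto3g STO-3G literature equilibrium geometry
H 0.000000 0.000000 0.000000
H 0.000000 0.000000 0.741400
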