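3
hcn_631g 6-31G literature equilibrium geometry
H 0.000000 0.000000 -1.064000
C 0.000000 0.000000 0.000000
N 0.000000 0.000000 1.156000
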