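2
H2 witness FCI/aug-cc-pVTZ (CCSD-equivalent for 2 electrons)
H 0.000000 0.000000 0.000000
H 0.000000 0.000000 0.741400
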