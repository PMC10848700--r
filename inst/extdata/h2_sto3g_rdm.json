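{
 "matrix": [
  [
   1.9745399697387,
   -4.2820958706662e-17
  ],
  [
   -4.2820958706662e-17,
   0.025460030261334
  ]
 ],
 "mo_space_size": 2,
 "frozen_indices": [],
 "active_indices": [
  0,
  1
 ],
 "n_active_electrons": 2,
 "provenance": "noise-free active-space FCI (2,2)/STO-3G; E=-1.13727017 Ha; generator make_fixtures.py"
}
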