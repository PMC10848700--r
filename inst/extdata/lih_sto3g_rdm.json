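{
 "matrix": [
  [
   1.9539264452403,
   0.065482013158878,
   -0.013305065200992
  ],
  [
   0.065482013158878,
   0.012327344205811,
   0.017944806723233
  ],
  [
   -0.013305065200992,
   0.017944806723233,
   0.033746210553839
  ]
 ],
 "mo_space_size": 6,
 "frozen_indices": [
  0
 ],
 "active_indices": [
  1,
  2,
  5
 ],
 "n_active_electrons": 2,
 "provenance": "noise-free active-space FCI (2,3)/STO-3G; E=-7.88114647 Ha; generator make_fixtures.py"
}
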