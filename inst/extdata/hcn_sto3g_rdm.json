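{
 "matrix": [
  [
   1.9222773430846,
   8.7377060102557e-17,
   0.0017883353408708,
   0.0012278831557679
  ],
  [
   9.0010062019097e-17,
   1.9222773430846,
   -0.0012278831557652,
   0.0017883353408648
  ],
  [
   0.0017883353408708,
   -0.0012278831557652,
   0.077722656915431,
   3.0985100485273e-17
  ],
  [
   0.0012278831557679,
   0.0017883353408648,
   3.1837109751092e-17,
   0.077722656915431
  ]
 ],
 "mo_space_size": 11,
 "frozen_indices": [
  0,
  1,
  2,
  3,
  4
 ],
 "active_indices": [
  5,
  6,
  7,
  8
 ],
 "n_active_electrons": 4,
 "provenance": "noise-free active-space FCI (4,4)/STO-3G; E=-91.77344322 Ha; generator make_fixtures.py"
}
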