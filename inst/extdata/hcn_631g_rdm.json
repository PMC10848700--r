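{
 "matrix": [
  [
   1.943506015786,
   -2.4794348432028e-17,
   0.0044405762190338,
   -0.0029767534239544
  ],
  [
   -2.5358472374899e-17,
   1.943506015786,
   -0.0029767534239561,
   -0.0044405762190328
  ],
  [
   0.0044405762190338,
   -0.0029767534239561,
   0.056493984214018,
   -2.5045917217362e-17
  ],
  [
   -0.0029767534239544,
   -0.0044405762190328,
   -3.1920436617278e-17,
   0.056493984214018
  ]
 ],
 "mo_space_size": 20,
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
 "provenance": "noise-free active-space FCI (4,4)/6-31G; E=-92.88864249 Ha; generator make_fixtures.py"
}
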