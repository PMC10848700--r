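{
 "matrix": [
  [
   1.832310727302,
   -1.136486751357e-15,
   1.6239343086529e-18,
   -2.9507809548097e-31
  ],
  [
   -1.136486751357e-15,
   0.043012965198283,
   -2.9264603807365e-33,
   4.3798886123558e-35
  ],
  [
   1.6239343086529e-18,
   -2.9264603807365e-33,
   0.062338153749857,
   -6.2610427983489e-17
  ],
  [
   -2.9507809548097e-31,
   4.3798886123558e-35,
   -6.2610427983489e-17,
   0.062338153749857
  ]
 ],
 "mo_space_size": 10,
 "frozen_indices": [
  0,
  1
 ],
 "active_indices": [
  2,
  3,
  4,
  5
 ],
 "n_active_electrons": 2,
 "provenance": "noise-free active-space FCI (2,4)/STO-3G; E=-14.66122606 Ha; generator make_fixtures.py"
}
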