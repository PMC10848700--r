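{
 "label": "lih_sto3g",
 "points_bohr": [
  [
   -0.09407927899246915,
   0.5405600618109911,
   2.895761014336819
  ],
  [
   1.4845108878799453,
   -0.4103207159492577,
   2.3426919441293226
  ],
  [
   -1.2014917686007704,
   1.0598246810296144,
   1.4082437866019117
  ],
  [
   0.8595648699932448,
   -1.4850690465825358,
   1.9116622351465766
  ],
  [
   0.6906086795656026,
   -0.009114417390934992,
   1.8800793588904572
  ],
  [
   -1.359817720111004,
   0.22595087057055085,
   2.0167146005020222
  ],
  [
   1.1748375653094962,
   -1.1323010353755858,
   1.6679053268291
  ],
  [
   -1.1949008351194834,
   -1.3652525152029353,
   2.5060478827158676
  ],
  [
   -0.6786167862404102,
   -1.0350089500852806,
   2.1290839572269684
  ],
  [
   -0.7005121805451959,
   -1.0613928475011578,
   0.45457182261740536
  ],
  [
   -0.18658576836844798,
   -0.35497132206622206,
   1.589313711160016
  ],
  [
   1.0503097774631627,
   -1.0752916536504609,
   2.3923232799748964
  ]
 ],
 "rho": [
  0.147871278152,
  0.022091302885,
  0.0144000168148,
  0.0153044062797,
  0.048246431835,
  0.0247314567594,
  0.0155801416213,
  0.0146795250074,
  0.0315075639785,
  0.0159106983724,
  0.0446521650093,
  0.0236620240075
 ]
}
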