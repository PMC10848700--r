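{
 "label": "h2_sto3g",
 "points_bohr": [
  [
   -1.1200454748373483,
   1.4164855307161592,
   -0.04886978193898428
  ],
  [
   -0.26348139642760504,
   -0.1460701920202956,
   0.3033333842080581
  ],
  [
   -1.3925060856200302,
   -0.5609358989145912,
   1.1320659323368945
  ],
  [
   1.4420586687636376,
   -0.07094620878278368,
   2.1478204142826716
  ],
  [
   1.1922303801034504,
   -0.9753536245871086,
   0.11929068839523382
  ],
  [
   -0.2541841659588182,
   0.6363654864834243,
   -0.4455518650413124
  ],
  [
   -0.3728013722426713,
   -1.2250977509462633,
   -0.04113272857155048
  ],
  [
   1.279923088516508,
   1.2228369632571514,
   1.7532742842598659
  ],
  [
   -1.141248024323509,
   -0.8443912647063855,
   0.3857828496042741
  ],
  [
   -0.4187002975015006,
   -1.3820298165662268,
   0.30263877667283245
  ],
  [
   0.2413878381420096,
   0.8408934401397934,
   0.4431839871400445
  ],
  [
   0.3553907106546408,
   -1.0531439317955933,
   1.8244196115214877
  ]
 ],
 "rho": [
  0.00954665247108,
  0.260296912429,
  0.0226228137725,
  0.0112142757359,
  0.0194919462073,
  0.0730726004825,
  0.0321353208147,
  0.00838590752507,
  0.0281932801597,
  0.0260837717055,
  0.0886921943078,
  0.0328524603231
 ]
}
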