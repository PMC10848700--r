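{
 "label": "li2_sto3g",
 "points_bohr": [
  [
   -0.1668219715207424,
   1.0632846363531114,
   2.0429187576886036
  ],
  [
   -0.08702355771073322,
   -0.38129267542479806,
   3.3834529140470218
  ],
  [
   -1.0028333740940334,
   0.29939768740949146,
   3.478675243762782
  ],
  [
   -1.3316848257731762,
   0.23621705056649933,
   3.3265849474476537
  ],
  [
   1.236284555828858,
   -0.8760036390296644,
   2.141946386959996
  ],
  [
   -1.4183512837787684,
   -0.7626854459532761,
   2.721969751572323
  ],
  [
   1.1122568400898385,
   -0.024914122553847395,
   3.09223801885584
  ],
  [
   -0.15753488690734896,
   0.5652164649530462,
   3.3504766758630122
  ],
  [
   -0.8869026859426649,
   -0.5960737235385516,
   2.4048407661533595
  ],
  [
   -0.9519432127762814,
   -0.9027198250503082,
   3.7632164814217806
  ],
  [
   0.9739882313329002,
   0.26683878891383417,
   1.1411347016136544
  ],
  [
   0.15083890153910895,
   -0.36032936618657097,
   2.4166165455097848
  ]
 ],
 "rho": [
  0.0127644792679,
  0.0150645869922,
  0.0125046721875,
  0.0111787392844,
  0.0105331668785,
  0.0100296153255,
  0.0125360114127,
  0.0144299940049,
  0.0129353604333,
  0.0110032357885,
  0.0138031744343,
  0.0154048013436
 ]
}
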