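{
 "label": "hcn_sto3g",
 "points_bohr": [
  [
   -1.2913169695071334,
   -0.43589841214508773,
   1.1776414585724753
  ],
  [
   0.4947705506240232,
   0.18012486797288974,
   -1.0143699841611982
  ],
  [
   0.37970265413803284,
   -0.26977440933958685,
   1.1336250192308424
  ],
  [
   0.2992579161894453,
   1.3657952585609072,
   0.4156257379371913
  ],
  [
   0.40286137215641205,
   -1.3423934692101827,
   -0.6181529435983569
  ],
  [
   0.5048292568397059,
   0.8837807901317678,
   0.8031335395019158
  ],
  [
   -1.0492803011321676,
   1.2846779629611769,
   -0.5120922331548056
  ],
  [
   0.9556820487051989,
   0.5213037056836107,
   -0.872403344101717
  ],
  [
   -0.3457826834924558,
   1.2867928737320473,
   -1.233092892140347
  ],
  [
   -0.5765520283940262,
   -0.4236514465797421,
   1.264043028003096
  ],
  [
   0.5278297343647136,
   0.8748192666337071,
   0.8227204755056382
  ],
  [
   -1.3588231815459242,
   0.04859043061326229,
   -0.7776049639289552
  ]
 ],
 "rho": [
  0.116378529392,
  0.216804099824,
  0.383831240185,
  0.106587108346,
  0.0812178331747,
  0.20078156366,
  0.0510403280375,
  0.118927867967,
  0.0597863650898,
  0.32356533363,
  0.200240280554,
  0.0794377381495
 ]
}
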