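{
 "label": "hcn_631g",
 "points_bohr": [
  [
   -0.43629119265530925,
   1.1948603579020656,
   0.5023559048169778
  ],
  [
   -1.1420498687682723,
   0.5747069706960248,
   1.4924103187926152
  ],
  [
   0.6910460963349614,
   0.3925942665611948,
   1.399950609318407
  ],
  [
   -1.2810604210604024,
   0.48881669197432553,
   0.5083511016239125
  ],
  [
   -0.6551453771130389,
   1.2194017233392618,
   -1.0254276066099415
  ],
  [
   -0.3540823133850939,
   -1.4445578419625749,
   -0.6400021874778753
  ],
  [
   0.3837474418094664,
   0.24199282042124115,
   -1.288007919632473
  ],
  [
   -1.379012193312056,
   0.6112506735037897,
   -0.7079032350233122
  ],
  [
   -0.6118390095042324,
   -0.26910665822117874,
   1.1162893129760352
  ],
  [
   1.2806747450942355,
   0.5536194846272555,
   -0.26258472493498236
  ],
  [
   1.085198088864559,
   0.41498622090196813,
   -1.0870144435508038
  ],
  [
   0.6008394929910201,
   -0.4430181285614361,
   -0.48396904319398176
  ]
 ],
 "rho": [
  0.117940878674,
  0.129052550882,
  0.294930680834,
  0.0988129914668,
  0.0607622746272,
  0.0636576382464,
  0.211427232447,
  0.0589752493993,
  0.319012559382,
  0.0879384347235,
  0.086646217466,
  0.217089844118
 ]
}
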