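{
 "label": "h2_witness_augccpvtz",
 "points_bohr": [
  [
   -1.3525855600329268,
   -0.26330515215600325,
   0.9867840601029112
  ],
  [
   -0.7648675666536527,
   0.28905608963570617,
   -0.7698124601163943
  ],
  [
   -0.6065963056726528,
   -0.8506944968917142,
   -0.5915982126041477
  ],
  [
   -0.5037721167812143,
   1.0465347533524065,
   1.6021960932457817
  ],
  [
   1.232042945660997,
   1.397172050123805,
   0.454491087695706
  ],
  [
   1.1134201894633975,
   -0.8260368511665103,
   0.4466384360075144
  ],
  [
   -0.30635990723583295,
   0.9197903687472424,
   0.6349217874967434
  ],
  [
   0.7046490444497189,
   0.803543302088531,
   0.5625987137608843
  ],
  [
   -1.2045224930044731,
   0.302275583265327,
   0.6605134667926722
  ],
  [
   0.317966896600375,
   -0.6884528717118331,
   0.1118910677622238
  ],
  [
   0.8750858249759892,
   1.2600224461643554,
   0.12364186491701068
  ],
  [
   1.1229374169571802,
   0.7523798191873885,
   1.668284209898595
  ]
 ],
 "rho": [
  0.0315404397007,
  0.0310329726153,
  0.0284879337962,
  0.0362331158481,
  0.0111561961058,
  0.0311727159816,
  0.0779827091188,
  0.0630507829068,
  0.0437011313303,
  0.10575738052,
  0.0203210944187,
  0.0228794967736
 ]
}
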