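{
 "h2_sto3g.molden": "8d82ee9dd206472a7ff4e38077e803d8",
 "h2_sto3g.xyz": "35333f844c1f68f6960b97eb0b041926",
 "h2_sto3g_rdm.json": "d348ad7398fbeefb557be298422aef69",
 "h2_sto3g_refpoints.json": "303d70f7a8a028fd4a30571e28f4c1a1",
 "h2_witness_augccpvtz.molden": "b3049f24934b22e4cd4351bafbb76c33",
 "h2_witness_augccpvtz.xyz": "082241f86aabd05c2da3947116bd1dc4",
 "h2_witness_augccpvtz_rdm.json": "1aa50429b763eaed167ded065acf9133",
 "h2_witness_augccpvtz_refpoints.json": "d33aa813cb773280dd07faa522534279",
 "hcn_631g.molden": "417c7c5b9b45efe23665570317749d10",
 "hcn_631g.xyz": "fb63081c4afa7d56cfd933e6dfee0311",
 "hcn_631g_rdm.json": "e73e1dd9e66afd791be39570369b52f0",
 "hcn_631g_refpoints.json": "39f862f45997462f8662532d87a8d125",
 "hcn_sto3g.molden": "b41353994c66a161b22b14a06bb70e5b",
 "hcn_sto3g.xyz": "d25744d85043f2aa02643db20d5f1372",
 "hcn_sto3g_rdm.json": "844f1c2c419cd527a1833328d3ac239a",
 "hcn_sto3g_refpoints.json": "bbeb82c28f311ee7d4100818ade31900",
 "li2_sto3g.molden": "8634b1ddd4a7e3ed77b86d7da53d2eef",
 "li2_sto3g.xyz": "14e4a3bd270018903836380ccd11afef",
 "li2_sto3g_rdm.json": "d6f662e09df0a407677f3ba448d7bded",
 "li2_sto3g_refpoints.json": "287f20284c91fbf429897ec7c5f69bd6",
 "lih_sto3g.molden": "25d445b0177b007f6cd8a616cf3f084a",
 "lih_sto3g.xyz": "cd40f115321724d5d49d25a9fad36ac7",
 "lih_sto3g_rdm.json": "09f9b2649e49a8a759b7325aabd728a7",
 "lih_sto3g_refpoints.json": "f90faf9b3691d61996e068b0c461316f"
}
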