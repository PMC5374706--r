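{
  "schema_version": 1,
  "features": ["hsa-miR-3607-3p", "hsa-miR-299-5p", "hsa-miR-365", "hsa-miR-513a-5p", "hsa-miR-29b-1*", "hsa-miR-340", "hsa-miR-1284", "hsa_SNORD6", "hsa-miR-934", "hsa-miR-3182", "hsa-miR-1908", "hsa-miR-155", "hsa-miR-23c", "hsa-miR-451", "hsa-miR-300", "hsa-miR-223", "hsa-miR-150", "hsa-miR-3613-3p"],
  "weights": [-2.4300000000000002, 2.0099999999999998, 1.7470000000000001, -2.4367999999999999, 2.2202000000000002, -1.4319, 1.8007, 1.7312000000000001, -2.2229999999999999, 1.8238000000000001, -1.1631, -1.5283, 1.3968, -1.2663, -1.4832000000000001, 1.0995999999999999, -0.77739999999999998, 1.3349],
  "threshold": -1.0024999999999999,
  "normalization": null,
  "params": [],
  "seed": null
}
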