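{
  "slope": 0.7334,
  "intercept": -2.4306,
  "n_fit": 41,
  "metrics": null,
  "provenance": "published calibration on a 41-GNP library with experimental octanol-water logP"
}
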