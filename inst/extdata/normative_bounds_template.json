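{
  "placeholder": true,
  "source": "TEMPLATE - replace with the normative 95% percentile intervals from the QST reference literature before screening",
  "hpt": [0, 0],
  "cpt": [0, 0],
  "mpt": [0, 0]
}
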