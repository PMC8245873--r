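{
  "n_compartments": 8,
  "dosing": 1,
  "plasma": 5,
  "storage": [6, 7]
}
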