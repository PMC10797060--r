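[
  {"name": "AD",    "kind": "binary",     "role": "shc"},
  {"name": "Depre", "kind": "binary",     "role": "shc"},
  {"name": "UTI",   "kind": "binary",     "role": "shc"},
  {"name": "FNCNR", "kind": "binary",     "role": "outcome"},
  {"name": "PCS",   "kind": "continuous", "role": "outcome"},
  {"name": "LiSAT", "kind": "ordinal",    "role": "outcome", "levels": [1, 2, 3, 4, 5, 6]},
  {"name": "Age",   "kind": "continuous", "role": "covariate"},
  {"name": "Sex",   "kind": "binary",     "role": "covariate"}
]
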