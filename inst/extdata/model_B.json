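{
  "variables": ["treatment", "cholesterol", "PBVC", "EDSS", "block_design", "MSIS29_physical"],
  "exogenous": ["treatment"],
  "edges": [
    ["treatment", "cholesterol"],
    ["treatment", "PBVC"],
    ["treatment", "EDSS"],
    ["treatment", "block_design"],
    ["treatment", "MSIS29_physical"],
    ["PBVC", "EDSS"],
    ["PBVC", "block_design"],
    ["PBVC", "MSIS29_physical"],
    ["EDSS", "MSIS29_physical"],
    ["block_design", "MSIS29_physical"]
  ]
}
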