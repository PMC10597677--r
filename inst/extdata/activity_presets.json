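{
  "bdelloid_characterized": [
    { "kind": "methyl_end_desaturation", "delta": 12 },
    { "kind": "methyl_end_desaturation", "delta": 15 },
    { "kind": "front_end_desaturation", "delta": 6 },
    { "kind": "front_end_desaturation", "delta": 5 },
    { "kind": "elongation", "substrate_carbons": [18, 20] }
  ],
  "elovl25": [
    { "kind": "elongation", "substrate_carbons": [18, 20] }
  ],
  "fed_d4": [
    { "kind": "front_end_desaturation", "delta": 4 }
  ],
  "fed_d5": [
    { "kind": "front_end_desaturation", "delta": 5 }
  ],
  "fed_d6": [
    { "kind": "front_end_desaturation", "delta": 6 }
  ],
  "fed_d8": [
    { "kind": "front_end_desaturation", "delta": 8 }
  ],
  "wx": [
    { "kind": "methyl_end_desaturation", "delta": 12 },
    { "kind": "methyl_end_desaturation", "delta": 15 }
  ]
}
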