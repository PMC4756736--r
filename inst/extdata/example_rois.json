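[
  {"center_mm": [0, 0],  "radius_mm": 4,  "role": "target"},
  {"center_mm": [25, 0], "radius_mm": 10, "role": "background"}
]
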