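[
  {"scale": 1.09, "rate": 0.171, "offset": 1.09, "role": "uptake", "group_id": "tolerant", "origin_dat": 14},
  {"scale": 110.2, "rate": 0.082, "offset": 22.2, "role": "rsa", "group_id": "tolerant", "origin_dat": 14},
  {"scale": 0.64, "rate": 0.150, "offset": 0.63, "role": "uptake", "group_id": "sensitive", "origin_dat": 14},
  {"scale": 108.1, "rate": 0.045, "offset": 37.4, "role": "rsa", "group_id": "sensitive", "origin_dat": 14}
]
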