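{
  "a11_v1": 0.1027,
  "a11_v2": 17,
  "a12": 1,
  "a13": 1,
  "b11_v1": 40,
  "b11_v2": 20,
  "b12": 1,
  "b13": 1,
  "a3_v1": 3.7933e-07,
  "a3_v2": 7.7000000000000002,
  "b3_v1": 0.0083999999999999995,
  "b3_v2": 100,
  "a2_v1": 9.1780000000000008,
  "a2_v2": 29.68,
  "ax": 0.050000000000000003,
  "bx": 0.022222222222222223
}
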