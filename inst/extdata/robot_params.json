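{
  "l1": 0.30, "l2": 0.25, "l3": 0.25,
  "lc1": 0.15, "lc2": 0.125, "lc3": 0.125,
  "m1": 1.0, "m2": 1.0, "m3": 0.8,
  "I1": 0.01, "I2": 0.01, "I3": 0.01,
  "B1": 0.1, "B2": 0.1, "B3": 0.1,
  "g": 9.81
}
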