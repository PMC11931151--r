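{
  "glucosidase": {
    "x1": 0.069, "x2": 0.077, "x3": 0.045,
    "x1:x2": -0.115, "x1:x3": -0.052, "x2:x3": -0.059,
    "x1:x2:x3": 0.200
  },
  "amylase": {
    "x1": 0.046, "x2": 0.068, "x3": 0.032,
    "x1:x2": -0.140, "x1:x3": 0.052, "x2:x3": -0.016,
    "x1:x2:x3": 3.110
  }
}
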