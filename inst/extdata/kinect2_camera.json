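{
  "fx": 365.6,
  "fy": 365.6,
  "cx": 255.5,
  "cy": 211.5,
  "unit_scale": 0.001,
  "box": {
    "min": [-0.8, -1.6, 1.5],
    "max": [0.8, 0.4, 3.1]
  }
}
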