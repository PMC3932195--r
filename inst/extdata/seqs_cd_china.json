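{
  "name": "Soil environmental quality standard II of China, cadmium (mg/kg)",
  "breakpoints": [0, 5.5, 6.5, 7.5, 14],
  "land_uses": ["paddy field", "dry farmland", "nonfarmland"],
  "thresholds": [
    [0.25, 0.30, 0.50, 1.00],
    [0.25, 0.30, 0.45, 0.80],
    [10.00, 10.00, 10.00, 10.00]
  ]
}
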