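{
  "agents": [
    {"agent": "inhibitorA", "Dm": 50, "m": 2, "unit": "nM"},
    {"agent": "inhibitorB", "Dm": 200, "m": 2, "unit": "nM"}
  ],
  "doses_per_agent": {
    "inhibitorA": [16.67, 32.73, 50, 76.38, 150],
    "inhibitorB": [66.67, 130.93, 200, 305.51, 600]
  },
  "timepoints": [0, 1, 2, 3, 4, 5],
  "noise_sd": 0.002,
  "replicates": 2,
  "seed": 20260924,
  "combination": {
    "ratio_fractions": [0.5, 0.5],
    "interaction": "loewe",
    "total_doses": [20, 40, 80, 160, 320]
  }
}
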