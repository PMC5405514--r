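{
  "reference_id": "celegans_TERT",
  "reference_length": 514,
  "note": "Approximate literature-based residue intervals (0-based, half-open) for C. elegans TERT (trt-1), which lacks a recognisable GQ/CP region and the CTE; override with exact coordinates where available.",
  "motifs": {
    "name":  ["QFP", "T",   "1",   "2",   "A",   "Bprime", "C",   "D",   "E"],
    "start": [95,    160,   190,   215,   265,   340,      385,   420,   450],
    "end":   [150,   185,   205,   235,   285,   365,      405,   440,   470]
  }
}
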