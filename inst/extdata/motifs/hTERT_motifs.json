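{
  "reference_id": "hTERT",
  "reference_length": 1132,
  "note": "Approximate literature-based residue intervals (0-based, half-open) for the canonical human TERT motifs; override with exact coordinates where available.",
  "motifs": {
    "name":  ["GQ",  "DAT", "linker", "CP",  "QFP", "T",   "1",   "2",   "A",   "Bprime", "C",   "D",   "E",   "CTE"],
    "start": [28,    90,    195,      405,   460,   560,   615,   636,   700,   820,      860,   895,   920,   941],
    "end":   [190,   130,   322,      450,   530,   595,   630,   660,   720,   845,      880,   915,   940,   1132]
  }
}
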