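{
  "pathway": "Wnt",
  "target_genes": [
    {"gene": "AXIN2", "direction": 1, "probes": ["AXIN2"]},
    {"gene": "LGR5", "direction": 1, "probes": ["LGR5"]},
    {"gene": "ASCL2", "direction": 1, "probes": ["ASCL2"]},
    {"gene": "SP5", "direction": 1, "probes": ["SP5"]},
    {"gene": "ZNRF3", "direction": 1, "probes": ["ZNRF3"]},
    {"gene": "DEFA6", "direction": 1, "probes": ["DEFA6"]},
    {"gene": "DKK1", "direction": 1, "probes": ["DKK1"]},
    {"gene": "EPHB2", "direction": 1, "probes": ["EPHB2"]},
    {"gene": "EPHB3", "direction": 1, "probes": ["EPHB3"]},
    {"gene": "CEMIP", "direction": 1, "probes": ["CEMIP"]},
    {"gene": "TCF7", "direction": 1, "probes": ["TCF7"]},
    {"gene": "TDGF1", "direction": 1, "probes": ["TDGF1"]}
  ],
  "reference_genes": ["REF1", "REF2", "REF3"]
}
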