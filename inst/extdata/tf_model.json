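{
  "comment": "Transcription-factor expression model: activity, per-subtype expression (off/low/high) and bound motif classes for the known rhodopsin regulators.",
  "factors": [
    {"name": "Otd", "activity": "activator",
     "expression": {"R1_6": "high", "pR7": "high", "yR7": "high", "pR8": "high", "yR8": "high"},
     "motifs": ["K50"]},
    {"name": "Pph13", "activity": "activator",
     "expression": {"R1_6": "high", "pR7": "high", "yR7": "high", "pR8": "high", "yR8": "high"},
     "motifs": ["Q50"]},
    {"name": "Ss", "activity": "activator",
     "expression": {"yR7": "high"},
     "motifs": ["XRE"]},
    {"name": "Dve", "activity": "repressor",
     "expression": {"R1_6": "high", "yR7": "low"},
     "motifs": ["K50"]},
    {"name": "Pros", "activity": "repressor",
     "expression": {"pR7": "high", "yR7": "high"},
     "motifs": ["Seq56"]},
    {"name": "Sens", "activity": "repressor",
     "expression": {"pR8": "high", "yR8": "high"},
     "motifs": ["S-box"]},
    {"name": "y_repressor", "activity": "repressor",
     "expression": {"yR7": "high", "yR8": "high"},
     "motifs": ["ATTC"]}
  ]
}
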