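{
  "comment": "Observed reporter expression patterns: five wild-type minimal promoters, fourteen hybrid promoters, and eight RCSI/RCSII swap or addition constructs. Levels: none (absent from the object), weak, strong, partial, variable.",
  "wildtype": {
    "Rh1": {"R1_6": "strong"},
    "Rh3": {"pR7": "strong"},
    "Rh4": {"yR7": "strong"},
    "Rh5": {"pR8": "strong"},
    "Rh6": {"yR8": "strong"}
  },
  "hybrids": [
    {"construct": "Rh4-Rh3", "observed": {"yR7": "strong"}, "note": "yR7-restricted, like wild-type Rh4"},
    {"construct": "Rh4-Rh5", "observed": {"yR7": "strong"}, "note": "yR7-restricted, like wild-type Rh4"},
    {"construct": "Rh4-Rh1", "observed": {"R1_6": "strong", "pR7": "strong", "yR7": "strong", "pR8": "strong", "yR8": "strong"}, "note": "broad expression in all photoreceptors"},
    {"construct": "Rh4-Rh6", "observed": {"R1_6": "variable", "yR7": "variable", "yR8": "variable"}, "note": "variable broadened expression (yR7, yR8, R1-R6)"},
    {"construct": "Rh1-Rh4", "observed": {"R1_6": "strong"}, "note": "R1-R6-restricted, like wild-type Rh1"},
    {"construct": "Rh5-Rh4", "observed": {"pR7": "strong", "pR8": "strong"}, "note": "novel pan-pale pattern (pR7 + pR8)"},
    {"construct": "Rh6-Rh4", "observed": {}, "note": "no detectable photoreceptor expression"},
    {"construct": "Rh3-Rh4", "observed": {"pR7": "strong", "yR7": "strong"}, "note": "pan-R7: addition of both donor patterns"},
    {"construct": "Rh3-Rh6", "observed": {"pR7": "strong", "yR7": "strong", "pR8": "strong", "yR8": "strong"}, "note": "pan-inner photoreceptor class pattern"},
    {"construct": "Rh3-Rh5", "observed": {"pR7": "strong"}, "note": "pR7-restricted, like wild-type Rh3"},
    {"construct": "Rh5-Rh3", "observed": {}, "note": "no detectable photoreceptor expression"},
    {"construct": "Rh6-Rh3", "observed": {"R1_6": "weak", "yR8": "variable"}, "note": "weak R1-R6 plus variable yR8 expression"},
    {"construct": "Rh5-Rh6", "observed": {"pR8": "partial"}, "note": "incomplete expression in a fraction of pR8s"},
    {"construct": "Rh6-Rh5", "observed": {}, "note": "no detectable photoreceptor expression"}
  ],
  "swaps": [
    {"construct": "Rh4-RCSIswap-Rh3", "context": "Rh4", "element": "RCSI", "donor": "Rh3", "mode": "swap",
     "observed": {"yR7": "strong", "pR7": "weak"}, "note": "faint derepression in a substantial fraction of pR7s"},
    {"construct": "Rh4-RCSIswap-Rh6", "context": "Rh4", "element": "RCSI", "donor": "Rh6", "mode": "swap",
     "observed": {"R1_6": "variable", "pR7": "variable", "yR7": "variable"}, "note": "variable expression in both R7 subtypes and R1-R6, not R8"},
    {"construct": "Rh3-RCSIswap-Rh6", "context": "Rh3", "element": "RCSI", "donor": "Rh6", "mode": "swap",
     "observed": {"pR7": "strong", "yR7": "strong"}, "note": "expansion into yR7s; no R8 expression"},
    {"construct": "Rh3-RCSIswap-Rh4", "context": "Rh3", "element": "RCSI", "donor": "Rh4", "mode": "swap",
     "observed": {"pR7": "strong"}, "note": "no obvious effect on pR7-specific expression"},
    {"construct": "Rh3-RCSIswap-Rh5", "context": "Rh3", "element": "RCSI", "donor": "Rh5", "mode": "swap",
     "observed": {"pR7": "strong", "yR7": "weak"}, "note": "derepression in yR7s"},
    {"construct": "Rh3-RCSIIswap-Rh4", "context": "Rh3", "element": "RCSII", "donor": "Rh4", "mode": "insert",
     "observed": {"pR7": "strong"}, "note": "RCSII addition alone has no effect"},
    {"construct": "Rh3-RCSI+IIswap-Rh4", "context": "Rh3", "element": "RCSI+II", "donor": "Rh4", "mode": "swap",
     "observed": {"pR7": "strong", "yR7": "strong"}, "note": "joint RCSI+RCSII swap causes derepression in most yR7s"},
    {"construct": "Rh6-RCSIswap-Rh4", "context": "Rh6", "element": "RCSI", "donor": "Rh4", "mode": "swap",
     "observed": {}, "note": "no detectable photoreceptor expression"}
  ]
}
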