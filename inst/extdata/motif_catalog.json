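{
  "comment": "Core cis-regulatory motif catalog for the rhodopsin promoters. Entries flagged 'placeholder' are user-replaceable stand-ins: the exact XRE, S-box and Seq56 consensus sequences are not established and should be supplied by the user for real scans.",
  "motifs": [
    {"name": "K50", "kind": "consensus", "consensus": "TAATCC", "role": "dual",
     "bound_factors": ["Otd", "Dve"], "region_class": "either"},
    {"name": "Q50", "kind": "consensus", "consensus": "TAATTR", "role": "activator",
     "bound_factors": ["Pph13"], "region_class": "either"},
    {"name": "RCSI_Rh1", "kind": "consensus", "consensus": "TAATTGAATTT", "role": "activator",
     "bound_factors": ["Otd", "Pph13"], "region_class": "proximal", "element": "RCSI"},
    {"name": "RCSI_Rh3", "kind": "consensus", "consensus": "TAATCCAATTC", "role": "dual",
     "bound_factors": ["Otd", "Pph13", "Dve"], "region_class": "proximal", "element": "RCSI"},
    {"name": "RCSI_Rh4", "kind": "consensus", "consensus": "TAATTGAATTT", "role": "activator",
     "bound_factors": ["Otd", "Pph13"], "region_class": "proximal", "element": "RCSI"},
    {"name": "RCSI_Rh5", "kind": "consensus", "consensus": "TAATTAGATTC", "role": "dual",
     "bound_factors": ["Otd", "Pph13"], "region_class": "proximal", "element": "RCSI"},
    {"name": "RCSI_Rh6", "kind": "consensus", "consensus": "TAATTGGATTA", "role": "dual",
     "bound_factors": ["Otd", "Pph13", "Dve"], "region_class": "proximal", "element": "RCSI"},
    {"name": "RCSII_Rh4", "kind": "consensus", "consensus": "GGTTG", "role": "activator",
     "bound_factors": ["Ss"], "region_class": "proximal", "element": "RCSII"},
    {"name": "P3", "kind": "consensus", "consensus": "TAATYNRATTA", "role": "activator",
     "bound_factors": ["Pph13"], "region_class": "proximal"},
    {"name": "ATTC", "kind": "consensus", "consensus": "ATTC", "role": "repressor",
     "bound_factors": ["y_repressor"], "region_class": "either"},
    {"name": "XRE", "kind": "consensus", "consensus": "TNGCGTG", "role": "activator",
     "bound_factors": ["Ss"], "region_class": "distal", "placeholder": true},
    {"name": "S-box", "kind": "consensus", "consensus": "AATCAR", "role": "repressor",
     "bound_factors": ["Sens"], "region_class": "either", "placeholder": true},
    {"name": "Seq56", "kind": "consensus", "consensus": "TAAGACG", "role": "repressor",
     "bound_factors": ["Pros"], "region_class": "distal", "placeholder": true}
  ]
}
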