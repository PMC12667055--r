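{
  "name": "sorl1_default",
  "protein_length": 2214,
  "comment": [
    "Default SORL1 (2,214 aa) domain architecture and residue-rule set.",
    "Segment boundaries follow the canonical domain annotation of the mature receptor.",
    "Per-repeat boundaries are NOT published; repeat starts are derived from the",
    "residue/repeat-position anchor pairs listed under 'anchors' (start = residue -",
    "position + 1) and all other boundaries are interpolated. Edit them freely:",
    "anything not pinned by an anchor is an explicit modelling choice, not a fact.",
    "The CR repeat 1 and 3Fn repeat 1 starts overhang their parent segment by 7 and",
    "10 residues respectively (both implied by anchors); overhangs up to",
    "'max_repeat_overhang' are accepted with a warning."
  ],
  "max_repeat_overhang": 10,
  "segments": [
    {"name": "signal_peptide", "start": 1,    "end": 28},
    {"name": "pro",            "start": 29,   "end": 81},
    {"name": "VPS10p",         "start": 82,   "end": 617},
    {"name": "10CC",           "start": 618,  "end": 753},
    {"name": "YWTD",           "start": 754,  "end": 1013},
    {"name": "EGF",            "start": 1014, "end": 1074},
    {"name": "CR_cluster",     "start": 1075, "end": 1550},
    {"name": "3Fn_cassette",   "start": 1551, "end": 2121},
    {"name": "TM_tail",        "start": 2122, "end": 2214}
  ],
  "repeats": [
    {"repeat_class": "L1_loop",    "index": 1,  "start": 380,  "end": 405,  "parent": "VPS10p"},
    {"repeat_class": "L2_loop",    "index": 1,  "start": 460,  "end": 490,  "parent": "VPS10p"},
    {"repeat_class": "YWTD_blade", "index": 1,  "start": 754,  "end": 794,  "parent": "YWTD"},
    {"repeat_class": "YWTD_blade", "index": 2,  "start": 795,  "end": 835,  "parent": "YWTD"},
    {"repeat_class": "YWTD_blade", "index": 3,  "start": 836,  "end": 875,  "parent": "YWTD"},
    {"repeat_class": "YWTD_blade", "index": 4,  "start": 876,  "end": 915,  "parent": "YWTD"},
    {"repeat_class": "YWTD_blade", "index": 5,  "start": 916,  "end": 956,  "parent": "YWTD"},
    {"repeat_class": "YWTD_blade", "index": 6,  "start": 957,  "end": 997,  "parent": "YWTD"},
    {"repeat_class": "CR",         "index": 1,  "start": 1068, "end": 1115, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 2,  "start": 1116, "end": 1150, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 3,  "start": 1151, "end": 1185, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 4,  "start": 1186, "end": 1220, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 5,  "start": 1221, "end": 1268, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 6,  "start": 1269, "end": 1304, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 7,  "start": 1305, "end": 1352, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 8,  "start": 1353, "end": 1400, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 9,  "start": 1401, "end": 1448, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 10, "start": 1449, "end": 1496, "parent": "CR_cluster"},
    {"repeat_class": "CR",         "index": 11, "start": 1497, "end": 1540, "parent": "CR_cluster"},
    {"repeat_class": "3Fn",        "index": 1,  "start": 1541, "end": 1636, "parent": "3Fn_cassette"},
    {"repeat_class": "3Fn",        "index": 2,  "start": 1637, "end": 1733, "parent": "3Fn_cassette"},
    {"repeat_class": "3Fn",        "index": 3,  "start": 1734, "end": 1829, "parent": "3Fn_cassette"},
    {"repeat_class": "3Fn",        "index": 4,  "start": 1830, "end": 1923, "parent": "3Fn_cassette"},
    {"repeat_class": "3Fn",        "index": 5,  "start": 1924, "end": 2018, "parent": "3Fn_cassette"},
    {"repeat_class": "3Fn",        "index": 6,  "start": 2019, "end": 2114, "parent": "3Fn_cassette"}
  ],
  "anchors": [
    {"residue": 1617, "repeat_class": "3Fn",        "index": 1, "position": 77},
    {"residue": 1619, "repeat_class": "3Fn",        "index": 1, "position": 79},
    {"residue": 1732, "repeat_class": "3Fn",        "index": 2, "position": 96},
    {"residue": 1816, "repeat_class": "3Fn",        "index": 3, "position": 83},
    {"residue": 2065, "repeat_class": "3Fn",        "index": 6, "position": 47},
    {"residue": 953,  "repeat_class": "YWTD_blade", "index": 5, "position": 38},
    {"residue": 1108, "repeat_class": "CR",         "index": 1, "position": 41},
    {"residue": 1261, "repeat_class": "CR",         "index": 5, "position": 41},
    {"residue": 1345, "repeat_class": "CR",         "index": 7, "position": 41}
  ],
  "thresholds": {
    "revel_threshold": 0.5,
    "maf_threshold": 5e-04,
    "dosage_threshold": 0.5,
    "splice_review_threshold": 0.2
  },
  "ptv_exon_rescue": [48],
  "exclusions": {
    "exons": [1],
    "residue_ranges": [{"start": 1, "end": 95}]
  },
  "rules": [
    {"label": "calcium_cage",          "scope_type": "repeat",  "scope": "CR",         "trigger": "fixed_position",        "positions": [37, 41, 47, 48], "priority": "high"},
    {"label": "asx_turn",              "scope_type": "repeat",  "scope": "CR",         "trigger": "fixed_position",        "positions": [44],             "priority": "high"},
    {"label": "ONC_cysteine",          "scope_type": "repeat",  "scope": "CR",         "trigger": "cysteine_gain_or_loss", "positions": [],               "priority": "high"},
    {"label": "tencc_cysteine",        "scope_type": "segment", "scope": "10CC",       "trigger": "cysteine_gain_or_loss", "positions": [],               "priority": "high"},
    {"label": "egf_cysteine",          "scope_type": "segment", "scope": "EGF",        "trigger": "cysteine_gain_or_loss", "positions": [],               "priority": "high"},
    {"label": "l1_cysteine",           "scope_type": "repeat",  "scope": "L1_loop",    "trigger": "cysteine_gain_or_loss", "positions": [],               "priority": "high"},
    {"label": "l2_cysteine",           "scope_type": "repeat",  "scope": "L2_loop",    "trigger": "cysteine_gain_or_loss", "positions": [],               "priority": "high"},
    {"label": "ywtd_motif",            "scope_type": "repeat",  "scope": "YWTD_blade", "trigger": "fixed_position",        "positions": [17, 18, 19, 20], "priority": "high"},
    {"label": "ywtd_conserved",        "scope_type": "repeat",  "scope": "YWTD_blade", "trigger": "fixed_position",        "positions": [29, 35],         "priority": "high"},
    {"label": "ywtd_partly_conserved", "scope_type": "repeat",  "scope": "YWTD_blade", "trigger": "fixed_position",        "positions": [9, 38],          "priority": "high"},
    {"label": "fn3_glycines",          "scope_type": "repeat",  "scope": "3Fn",        "trigger": "fixed_position",        "positions": [36, 96],         "priority": "high"},
    {"label": "fn3_hydrophobic_core",  "scope_type": "repeat",  "scope": "3Fn",        "trigger": "fixed_position",        "positions": [25, 41],         "priority": "high"},
    {"label": "tyrosine_corner",       "scope_type": "repeat",  "scope": "3Fn",        "trigger": "fixed_position",        "positions": [77, 79, 83],     "priority": "high"},
    {"label": "vps10p_revel",          "scope_type": "segment", "scope": "VPS10p",     "trigger": "revel_at_least",        "positions": [],               "priority": "high"},
    {"label": "tencc_revel",           "scope_type": "segment", "scope": "10CC",       "trigger": "revel_at_least",        "positions": [],               "priority": "high"},
    {"label": "fn3_prolines",          "scope_type": "repeat",  "scope": "3Fn",        "trigger": "fixed_position",        "positions": [6, 7],           "priority": "moderate"}
  ]
}
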