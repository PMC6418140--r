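[
  {
    "id": "fix001",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 2,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  },
  {
    "id": "fix002",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": true,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  },
  {
    "id": "fix003",
    "planted_category": "high_confidence",
    "planted_violation": "r5_star_reads",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  },
  {
    "id": "fix004",
    "planted_category": "rejected",
    "planted_violation": "r2_r3",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix005",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": -2,
    "planted_isomirs": 1,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix006",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": true,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 27],
    "star": [36, 57]
  },
  {
    "id": "fix007",
    "planted_category": "high_confidence",
    "planted_violation": "r5_star_reads",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix008",
    "planted_category": "rejected",
    "planted_violation": "r2_r3",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 27],
    "star": [36, 57]
  },
  {
    "id": "fix009",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 2,
    "planted_isomirs": 0,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix010",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": true,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 1,
    "mature": [6, 27],
    "star": [36, 57]
  },
  {
    "id": "fix011",
    "planted_category": "high_confidence",
    "planted_violation": "r5_star_reads",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 27],
    "star": [36, 57]
  },
  {
    "id": "fix012",
    "planted_category": "rejected",
    "planted_violation": "r2_r3",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix013",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": -2,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  },
  {
    "id": "fix014",
    "planted_category": "very_high_confidence",
    "planted_violation": "none",
    "planted_conserved": true,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  },
  {
    "id": "fix015",
    "planted_category": "high_confidence",
    "planted_violation": "r7_mfe",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 1,
    "mature": [6, 26],
    "star": [35, 55]
  },
  {
    "id": "fix016",
    "planted_category": "rejected",
    "planted_violation": "r2_r3",
    "planted_conserved": false,
    "planted_lfc_M_vs_Y": 0,
    "planted_isomirs": 0,
    "mature": [6, 25],
    "star": [34, 53]
  }
]
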