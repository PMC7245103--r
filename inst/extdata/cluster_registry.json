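{
  "building_blocks": [
    {"label": "Mo1", "mo_count": 1, "non_mo_note": "mononuclear molybdate unit"},
    {"label": "Mo2", "mo_count": 2, "non_mo_note": "generic dinuclear unit (corner/edge variant unspecified)"},
    {"label": "Mo2c", "mo_count": 2, "non_mo_note": "corner-shared dimer; feeds the {Mo154} wheel family"},
    {"label": "Mo2e", "mo_count": 2, "non_mo_note": "edge-shared reduced dimer; feeds the {Mo132} Keplerate"},
    {"label": "Mo3", "mo_count": 3, "non_mo_note": "trinuclear unit postulated in Keggin assembly"},
    {"label": "Mo6", "mo_count": 6, "non_mo_note": "hexanuclear building block"},
    {"label": "Mo8", "mo_count": 8, "non_mo_note": "octanuclear unit with central pentagonal MoO7 bipyramid"},
    {"label": "PMo6", "mo_count": 6, "non_mo_note": "phosphate-centred hexamolybdate fragment postulated in Keggin assembly"},
    {"label": "Ce-unit", "mo_count": 0, "non_mo_note": "Ce(H2O)5 unit; contributes no Mo"}
  ],
  "clusters": [
    {
      "name": "{PMo12}",
      "nuclearity": 12,
      "mo_vi": 10,
      "mo_v": 2,
      "heteroatoms": {"P": 1},
      "note": "Keggin ion as the 2-electron-reduced host of compound 1, (PMo(VI)10Mo(V)2O40)"
    },
    {
      "name": "{Mo36}",
      "nuclearity": 36,
      "mo_vi": 36,
      "mo_v": 0,
      "note": "fully oxidized template cluster, [Mo(VI)36O112(H2O)16]8-"
    },
    {
      "name": "{Mo57M}",
      "nuclearity": 57,
      "heteroatoms": {"M": 6},
      "note": "nuclearity-only record; M = transition-metal heteroatom, 6 NO ligands"
    },
    {
      "name": "{Mo132}",
      "nuclearity": 132,
      "mo_vi": 72,
      "mo_v": 60,
      "note": "Keplerate ball, [Mo(VI)72Mo(V)60O372(CH3COO)30(H2O)72]42-"
    },
    {
      "name": "{Mo150}",
      "nuclearity": 150,
      "mo_vi": 130,
      "mo_v": 20,
      "note": "wheel templated by a central {Mo36}, [Mo(VI)130Mo(V)20O442(OH)10(H2O)60]14-"
    },
    {
      "name": "{Mo154}",
      "nuclearity": 154,
      "note": "molybdenum-blue wheel, [Mo154O462H14(H2O)70]14-; valence split not recorded"
    },
    {
      "name": "{Mo248}",
      "nuclearity": 248,
      "note": "capped wheel; nuclearity-only record"
    },
    {
      "name": "{Mo368}",
      "nuclearity": 368,
      "heteroatoms": {"S": 48},
      "note": "lemon-shaped cluster with 48 sulfate ligands; nuclearity-only record"
    },
    {
      "name": "{Mo124Ce4}",
      "composition": {"Mo8": 12, "Mo2": 8, "Mo1": 12},
      "mo_vi": 100,
      "mo_v": 24,
      "heteroatoms": {"Ce": 4, "P": 0},
      "note": "compound-1 nanoring hosting a {PMo12} Keggin; 24-electron-reduced ring with 4 cystine ligands"
    }
  ]
}
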