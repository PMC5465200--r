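[
  {"label": "C2-M217",        "parent": "Y",          "marker": "M217"},
  {"label": "C2b1a2-M48",     "parent": "C2-M217",    "marker": "M48"},
  {"label": "C2b1b-M128",     "parent": "C2-M217",    "marker": "M128"},
  {"label": "D-M174",         "parent": "Y",          "marker": "M174"},
  {"label": "E1b1b1-M35.1",   "parent": "Y",          "marker": "M35.1"},
  {"label": "E1b1b1a1-M78",   "parent": "E1b1b1-M35.1", "marker": "M78"},
  {"label": "E1b1b1b2a-M123", "parent": "E1b1b1-M35.1", "marker": "M123"},
  {"label": "G1-M285",        "parent": "Y",          "marker": "M285"},
  {"label": "G2a-P15",        "parent": "Y",          "marker": "P15"},
  {"label": "G2a2b1-M406",    "parent": "G2a-P15",    "marker": "M406"},
  {"label": "G2a2b2a-P303",   "parent": "G2a-P15",    "marker": "P303"},
  {"label": "H-M69",          "parent": "Y",          "marker": "M69"},
  {"label": "I-M170",         "parent": "Y",          "marker": "M170"},
  {"label": "J1-M267",        "parent": "Y",          "marker": "M267"},
  {"label": "J1a2b-P58",      "parent": "J1-M267",    "marker": "P58"},
  {"label": "J2-M172",        "parent": "Y",          "marker": "M172"},
  {"label": "J2a1b-M67",      "parent": "J2-M172",    "marker": "M67"},
  {"label": "J2a1b1-M92",     "parent": "J2a1b-M67",  "marker": "M92"},
  {"label": "J2a1h-M47",      "parent": "J2-M172",    "marker": "M47"},
  {"label": "J2b-M12",        "parent": "J2-M172",    "marker": "M12"},
  {"label": "L-M20",          "parent": "Y",          "marker": "M20"},
  {"label": "N-LLY22g",       "parent": "Y",          "marker": "LLY22g"},
  {"label": "N1c1-M178",      "parent": "N-LLY22g",   "marker": "M178"},
  {"label": "O1a-M119",       "parent": "Y",          "marker": "M119"},
  {"label": "O1b-P31",        "parent": "Y",          "marker": "P31"},
  {"label": "O2-M122",        "parent": "Y",          "marker": "M122"},
  {"label": "O2a2-P201",      "parent": "O2-M122",    "marker": "P201"},
  {"label": "O2a2b1-M134",    "parent": "O2a2-P201",  "marker": "M134"},
  {"label": "Q-M242",         "parent": "Y",          "marker": "M242"},
  {"label": "R1a1a-M198",     "parent": "Y",          "marker": "M198"},
  {"label": "R1a1a1b1a1-M458","parent": "R1a1a-M198", "marker": "M458"},
  {"label": "R1b-M343",       "parent": "Y",          "marker": "M343"},
  {"label": "R1b1a1a2-M269",  "parent": "R1b-M343",   "marker": "M269"},
  {"label": "R2a-M124",       "parent": "Y",          "marker": "M124"},
  {"label": "T1a-M70",        "parent": "Y",          "marker": "M70"}
]
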