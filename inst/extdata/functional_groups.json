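{
  "comment": "Representative functional-group SMARTS patterns for group-contribution style modelling; load with loadRecipe() or pass to smartsCountSpec().",
  "descriptors": [],
  "groups": [
    {"name": "grp_carbon", "smarts": "[#6]"},
    {"name": "grp_ch3", "smarts": "[CX4H3]"},
    {"name": "grp_ch2", "smarts": "[CX4H2]"},
    {"name": "grp_aromatic_c", "smarts": "c"},
    {"name": "grp_aromatic_n", "smarts": "n"},
    {"name": "grp_hydroxyl", "smarts": "[OX2H]"},
    {"name": "grp_phenol_oh", "smarts": "[OX2H][c]"},
    {"name": "grp_ether", "smarts": "[OD2]([#6])[#6]"},
    {"name": "grp_carbonyl", "smarts": "[CX3]=[OX1]"},
    {"name": "grp_carboxyl", "smarts": "[CX3](=O)[OX2H1]"},
    {"name": "grp_carboxylate", "smarts": "[CX3](=O)[O-]"},
    {"name": "grp_ester", "smarts": "[CX3](=O)[OX2H0][#6]"},
    {"name": "grp_amide", "smarts": "[NX3][CX3]=[OX1]"},
    {"name": "grp_primary_amine", "smarts": "[NX3;H2;!$(NC=O)]"},
    {"name": "grp_ammonium", "smarts": "[NX4+]"},
    {"name": "grp_nitrile", "smarts": "[NX1]#[CX2]"},
    {"name": "grp_nitro", "smarts": "[$([NX3](=O)=O),$([NX3+](=O)[O-])]"},
    {"name": "grp_fluoro", "smarts": "[F]"},
    {"name": "grp_chloro", "smarts": "[Cl]"},
    {"name": "grp_bromo", "smarts": "[Br]"},
    {"name": "grp_sulfur", "smarts": "[#16]"},
    {"name": "grp_ring_atom", "smarts": "[R]"}
  ]
}
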