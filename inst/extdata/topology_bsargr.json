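{
  "trimer1_chains": ["A", "B", "C"],
  "trimer2_chains": ["D", "E", "F"],
  "pairing": [
    ["A", "F"],
    ["B", "E"],
    ["C", "D"]
  ],
  "com_residue_range": [85, 149],
  "n_domain_range": [1, 71],
  "c_domain_range": [72, 149],
  "probe_atoms": {
    "K75_amine": {
      "resno": 75,
      "atoms": "NZ"
    },
    "R78_guanidino": {
      "resno": 78,
      "atoms": ["NH1", "NH2", "NE"]
    },
    "D82_carboxylate": {
      "resno": 82,
      "atoms": ["OD1", "OD2"]
    },
    "D82_backbone_O": {
      "resno": 82,
      "atoms": "O"
    },
    "ARG43_CA": {
      "resno": 43,
      "atoms": "CA"
    }
  }
}
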