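{
  "comment": "Published fixed-charge monovalent cation Lennard-Jones parameters (CHARMM convention: epsilon in kcal/mol, rmin is Rmin/2 in Angstrom). Pair-specific overrides (NBFIX-style) go under nbfix, keyed by ligand atom class.",
  "Na": {"epsilon": 0.0469, "rmin": 1.36375, "nbfix": {}},
  "K":  {"epsilon": 0.0870, "rmin": 1.76375, "nbfix": {}}
}
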