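{
  "id": "high_field",
  "seed": 2024,
  "n_ligands": 6,
  "ligand_charges": [-1, -1, 0, 0, 0, 0],
  "protonated": [false, false, false, false, false, false],
  "mutated": [false, false, false, false, false, false],
  "ion": "Na",
  "temperature": 303.15,
  "confinement_radius": 5.0,
  "wall_k": 10,
  "restraint": {"k_r": 10, "k_theta": 200, "k_psi": 200},
  "sampling": {"n_steps": 2000, "thin": 5},
  "droplet": {"n_solvent": 12, "radius": 6.0}
}
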