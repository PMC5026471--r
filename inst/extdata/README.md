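# Packaged fixture tables

Small plain-text reference tables used by the reporting layer and the test
suite.  All energies are kcal/mol, angles degrees, temperatures Kelvin.

- `ion_defaults.json` — default Lennard-Jones parameters for the Na+ and K+
  fixed-charge ion models (CHARMM Rmin/2 convention) with room for
  pair-specific (NBFIX-style) overrides.
- `site_selectivity_reference.tsv` — reference binding free-energy differences
  ddG(Na->K) per binding site (I/II/III) for the wildtype and
  charge-neutralizing-mutant pump systems in their E1/E2/P-E2 states, as
  obtained from published FEP/H-REMD calculations on the reduced pump
  binding-site systems.  E2-state systems have two sites only.
- `boosting_parameters_reference.tsv` — fitted boosting-potential parameters (cosine-series
  coefficients k_n in kcal/mol and phases chi0_n in degrees) for each
  binding-site residue's chi1 torsion; `n_terms` is the series length (3-6).
  A trailing `p` in the residue label marks the protonated form; `N`-prefixed
  labels are the D-to-N mutants.  The printed source table runs some cells
  together; splits follow the decimal conventions of the unambiguous rows.
- `pka_cycle_inputs.tsv` — inputs of the pKa thermodynamic cycle worked example:
  deprotonation free-energy legs at the binding site and in bulk water, the
  bulk reference pKa of an aspartate, plus the reference bulk-phase
  Na->K transformation free energy.
- `checksums.tsv` — content checksums verified by `load_fixture_tables()`.
- `scenarios/` — example scenario configurations for `run_scenario()`.
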