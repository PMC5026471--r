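Package: pumpsel
Title: Ion Selectivity of Flexible Binding Sites by Alchemical Free Energy Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale free-energy machinery for studying how protonation and
    occlusion control Na+/K+ selectivity in flexible ion binding sites such as
    those of the Na+/K+-pump.  Provides reduced binding-site and bulk-droplet
    Hamiltonians with dipolar, protonatable coordinating ligands, a Metropolis
    Monte Carlo sampler, umbrella sampling of side-chain-like torsions,
    boosting potentials fitted as cosine series to torsional potentials of
    mean force, a two-dimensional Hamiltonian replica-exchange topology
    (alchemical coupling x boost strength), weighted-histogram (WHAM/MBAR)
    estimators with block-error analysis, and the thermodynamic
    post-processing that converts alchemical legs into standard-state binding
    free energies, dissociation-constant ratios, and pKa shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
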