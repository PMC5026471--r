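---
title: "Methods: alchemical selectivity free energies on reduced binding-site models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical selectivity free energies on reduced binding-site models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pumpsel` re-implements, at desk scale, the free-energy methodology used to
establish that the ion selectivity of the Na⁺/K⁺-pump binding pocket is
controlled by the protonation state of its coordinating residues and by the
conformational (occlusion) state of the pump.  This vignette documents the
models, the tunable parameters, the estimators, and the design decisions
that were genuinely open.

## The reduced binding-site model

The production calculations behind this methodology run on "reduced"
systems: an explicit inner region around the binding pocket embedded in an
implicit boundary potential.  `pumpsel` replaces that construction with a
minimal Hamiltonian that preserves the contracts the estimators rely on —
a confined mobile cation, a small number of flexible dipolar coordinating
ligands with multi-well side-chain-like torsions, and a finite sampling
volume:

* **Ligands** (`ligand_spec`): a rigid arm on a fixed anchor carrying a
  dipole (+q at the base, −q at the tip, default q = 0.55 e, arm 2.0 Å,
  cone half-angle 60°) whose orientation swings with one torsion χ.  The
  intrinsic torsion potential is a cosine series; the default
  `k = (1.5, 0.8)` kcal/mol with multiplicities `(3, 1)` gives three
  unequal rotamer wells with ~3 kcal/mol barriers — deep enough that
  boosting demonstrably matters, shallow enough to cross occasionally
  unaided.
* **Protonation** (`protonated` flag): an acidic ligand carries an extra
  formal −1 e on its tip when deprotonated; protonation neutralises it and
  changes *charges only*.  The D→N-style mutation surrogate (`mutated`)
  neutralises the tip and adds +0.2 Å to its Lennard-Jones radius — a
  bulkier but neutral amide in place of a charged oxygen.
* **Ions**: published fixed-charge monovalent LJ parameters (packaged in
  `ion_defaults.json`; CHARMM Rmin/2 convention), with pair-specific
  (NBFIX-style) overrides representable per ligand atom class, because the
  alchemical interpolation must cover them.
* **Confinement**: a half-harmonic spherical wall (radius 5 Å, 10
  kcal/mol/Å²) stands in for the boundary potential: it fixes the sampling
  volume without any electrostatic continuum machinery, which is out of
  scope here.
* **Restraint** (`restraint_spec`): the translational restraint
  `u_trans = ½[k_r(r−r₀)² + k_θ(θ−θ₀)² + k_ψ(ψ−ψ₀)²]` ties the ion to
  three fixed anchor points p₁–p₃, with the protocol stiffness
  k_r = 10 kcal/mol/Å² and k_θ = k_ψ = 200 kcal/mol/rad².  Equilibrium
  values are measured from the reference pose, mirroring how they are
  taken from an equilibrated structure in the original protocol.

The **bulk droplet** (`bulk_droplet_model`) represents the solution phase:
point-dipole solvent "molecules" (q = 0.417 e at 1.2 Å separation, a
water-like 2.4 D dipole; water-oxygen-like LJ centre) in a wall-bounded
sphere, holding either the ion (bulk swap leg) or a protonatable solute
(bulk deprotonation leg).  A weak 0.5 kcal/mol/Å² central restraint keeps
the ion near the droplet centre, as in the reference protocol.

All constants are fixed package-wide: Coulomb constant 332.0716
kcal·Å/(mol·e²), k_B = 0.0019872041 kcal/mol/K, T = 303.15 K (RT =
0.60242 kcal/mol), standard state 1 molecule / 1661 Å³.  Angles are degrees
at every interface and radians internally.

## What the generator emulates — and what it does not

The toy systems reproduce the *statistical structure* the estimators
assume: a bound ion whose exchange with its coordinating shell is slow on
the move scale, side-chain torsions with multiple metastable rotamers (so
zero-boost sampling is bottlenecked and replica exchange helps), two ion
species differing only in nonbonded parameters, and a bulk reference phase
with its own solvent relaxation.  They do **not** emulate atomistic detail:
no backbone, no explicit water at the site, no polarisation, no membrane,
and the droplet is far smaller than a real hydration shell.  Passing tests
therefore validates the estimators, protocols, and thermodynamic plumbing —
not the quantitative selectivity of any real pump state.  Absolute ΔΔG
values from `run_scenario` carry multi-kcal/mol block errors at the default
problem sizes; the physically meaningful, sign-stable observable is the
*paired* response to protonation (the acceptance battery's field-shift
check), which is the mechanism the methodology exists to expose:
deprotonated (high-field) ligands pull the balance towards Na⁺.

## Sampling

`run_mc` is a Metropolis Monte Carlo sampler, not a dynamics integrator:
every estimator downstream consumes equilibrium averages only, so "ns"
budgets in the original protocol map to MC step counts here.  The move set
mixes Gaussian ion displacements, uniform single-torsion rotations, and
(for droplets) solvent translations/rotations.  A pre-run of 400–600 steps
tunes each move size towards 30–50% acceptance and is then frozen, so
production obeys detailed balance exactly; identical `(model, seed,
n_steps)` give bit-identical series.  Angular bias differences are wrapped
to (−180°, 180°] before squaring, matching the periodicity of χ.

Umbrella sampling (`umbrella_scan`) uses the protocol defaults of 72
windows at 5° spacing with a 100 kcal/mol/rad² harmonic bias.  Torsional
PMFs destined for boosting fits are produced on the isolated
single-torsion model (`torsion_model`), mirroring how the original
protocol isolates one residue on its helix before scanning χ — and making
the scan cheap enough for property tests at full protocol fidelity.

## Estimators

`wham_multistate` solves the binless WHAM/multistate-reweighting equations:
per-state free energies are the fixed point of the self-consistency
relations over a frames × states cross-energy matrix.  Because plain
fixed-point iteration converges arbitrarily slowly when overlap is thin
(small per-block subsets especially), the implementation first takes damped
Newton steps on the convex objective whose stationarity conditions are
exactly those equations, then polishes with self-consistent iteration until
the change in every free energy is below 10⁻⁸ kcal/mol (cap 10⁵
iterations; non-convergence is an error, never a silent result).  The
reported per-state effective sample sizes act as the overlap diagnostic: a
warning fires below 50 frames.

`wham_umbrella` is the histogram (2°-bin default) WHAM on the periodic χ
grid, anchored at the PMF minimum; unvisited bins are `NA`, and fits or
RMS comparisons simply exclude them.  `block_error` is the sample standard
deviation across 10 contiguous block estimates — deliberately the *SD*,
not the SEM, so error bars follow the same convention as the reference
selectivity tables they are compared against.

The boosting fit (`fit_boosting_potential`) expands each cosine term as
`a_n cos(nχ) + b_n sin(nχ)` plus a free constant, making the fit a convex
linear least-squares problem, then converts to amplitudes
`k_n = √(a_n²+b_n²) ≥ 0` and phases `χ₀,n = atan2(b_n, a_n)/n`.  The "+1"
inside each term is absorbed into the fitted constant and restored on
evaluation, so `evaluate_boost` matches the series definition literally.
Model selection minimises the RMS residual over N = 3…6 terms with ties to
the smaller N.  Phases are only defined modulo 360°/n, and a negative
source amplitude is equivalent to a half-period phase shift; round-trip
checks therefore compare amplitudes and evaluated curves, not raw phases.

## Alchemical legs

The Na⁺→K⁺ transformation interpolates ε, Rmin/2 and every pair override
linearly in λ (charge fixed at +1).  The **three-point protocol** samples
λ = 0, the mid-point hybrid, and λ = 1, cross-evaluates every frame under
all three parameter sets, and reads the two adjacent differences off the
converged multistate WHAM ("solved self-consistently" is implemented as
exactly that fixed point, equivalently iterated Bennett); their sum is the
reported leg.  Restraint decoupling scales `u_trans` linearly along its
schedule, and the deprotonation legs scale the tip formal charge —
charges only, no topology change, which is all the site-vs-bulk pKa
difference requires.  Default window counts follow the reference protocol
(16 site swap, 11 bulk swap, 24/10 deprotonation); the replica topology
couples each λ window to boost levels scaled 0→1 with exchanges allowed
only between adjacent boost levels within a window and between adjacent
windows at zero boost.  λ values and boost strengths are evenly spaced —
the protocol states the ranges but not the spacing, and even spacing is
the simplest defensible choice.  One sweep attempts every allowed edge
once, even-indexed edges then odd-indexed.  Only zero-boost replicas feed
the estimators.

The rigid-rotor factor uses the Gaussian closed form
`F_t = r₀² sinθ₀ (2πk_BT)^{3/2} / (k_r k_θ k_ψ)^{1/2}`.  The literature
source for this correction does not print the formula, so the quadrature
oracle — not the formula — is the contract: every use is validated against
direct integration of `∫ r² sinθ e^{−u_trans/k_BT}`.  The leading Laplace
correction to the radial integral is `1/(β k_r r₀²)` (~0.5% at
k_r = 10 kcal/mol/Å², r₀ = 3.5 Å), so the 0.5%-agreement domain covers
k_r ≥ ~10 and angular constants ≥ ~200 kcal/mol/rad²; the property grid
spans two decades within that domain.

## Problem sizes and numerical choices

Default desk-scale budgets: 2 000–4 000 MC steps per alchemical state
(thinning 4–10), 8 000–12 000 steps per umbrella window on the isolated
torsion, and a 12-dipole droplet — each full scenario runs in about a
minute and the complete test suite plus acceptance script in a few
minutes.  Degenerate inputs are defined rather than accidental: identical
states give exactly zero free-energy differences; a zero-stiffness
restraint decouples at zero cost; `strength = 0` boosts leave energies
bit-identical; a single unbiased window reduces umbrella WHAM to the
direct histogram estimate.  A single window with zero bias is accepted
(the window type nominally requires positive stiffness) precisely so that
degenerate identity is expressible.

## Other design decisions

* Scenario labels follow the glutamate set E327/E779/E954; the source
  material names the third-glutamate set inconsistently in one place, and
  nothing in the package depends on which reading is correct.
* The packaged boosting-parameter table was transcribed from a source whose
  printed layout runs cells together; splits follow the decimal
  conventions of the unambiguous rows, and the fixture README flags the
  affected entries.
* The command-line surface is the R API plus `scripts/acceptance.R`; this
  is an analysis package whose users work from R, so no shell subcommand
  wrapper is shipped.
* Reports are deterministic files (TSV + JSON metadata with a config hash
  and seed), so every number in a report is recomputable from its
  provenance record.

## Known limitations

Pure-R energy evaluation caps throughput near 10⁴ MC steps per second per
state on one core; absolute binding free energies at these budgets carry
±2–4 kcal/mol block errors.  The droplet is too small to reproduce bulk
solvation free energies quantitatively (its Na⁺→K⁺ leg is used only inside
paired differences).  The H-REMD driver holds all replica states in memory
and is intended for the reduced models, not for large replica counts with
expensive Hamiltonians.  And the three-point protocol assumes the hybrid
mid-point overlaps both endpoints; the effective-sample-size warning is the
guard, not a guarantee.
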