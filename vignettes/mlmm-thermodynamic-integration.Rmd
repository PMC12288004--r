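---
title: "Hybrid ML/MM simulation and thermodynamic integration with an indivisible ML potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ML/MM simulation and thermodynamic integration with an indivisible ML potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmmti)
```

## The model

`mlmmti` simulates systems whose potential energy is partitioned into
three parts,

$$E_\text{total} = E_\text{ML} + E_\text{MM} + E_\text{ML-MM},$$

where one region (typically a whole ligand) is described by a
machine-learning interatomic potential (MLIP), the remainder by a
classical force field (harmonic bonds and angles, cosine dihedrals,
Lennard-Jones and Coulomb nonbonded terms with 1-2/1-3 exclusions and
AMBER-convention 1-4 scaling), and the two regions interact through
*mechanical embedding*: a plain Coulomb-plus-LJ sum over all
cross-region atom pairs,

$$E_\text{ML-MM} \;=\; \sum_{i\in\mathrm{MM}}\sum_{j\in\mathrm{ML}}
  \frac{q_i q_j}{r_{ij}} \;+\;
  \sum_{i\in\mathrm{MM}}\sum_{j\in\mathrm{ML}}
  \left[\frac{A_{ij}}{r_{ij}^{12}} - \frac{B_{ij}}{r_{ij}^{6}}\right].$$

No polarization of the ML region by MM charges is attempted, and no
covalent bond may cross the region boundary (whole-molecule ML regions
only; link atoms are out of scope).

The central design constraint is the **ML-potential contract**
(`surrogate_ml_potential()`, or any user function with the same shape):
the evaluator returns *one* scalar energy and its negative-gradient
forces, with no bonded/nonbonded decomposition. Trained MLIPs expose
exactly this interface, and every algorithm in the package is written
against it — nothing downstream may peek inside the ML energy.

Because no trained network is usable at desk scale, the package ships a
*surrogate* ML potential: classical bond/angle/dihedral/nonbonded terms
over the ML atoms folded into one opaque closure. It is a stand-in
obeying the same contract, not an approximation of any particular
trained model. Two fidelity details matter:

* **Reference energies.** Trained potentials return total energies that
  include atomic reference (self) energies of their quantum-chemistry
  labels, so even a small molecule evaluates to hundreds of thousands of
  negative kcal/mol. The surrogate accepts per-element
  `reference_energies` and the toy-solute generator installs
  Hartree-scale atomic values (C −23742, N −34256, O −47109, H −314
  kcal/mol). The offset is configuration-independent and cancels in
  every difference the package computes; it matters only for quantities
  *normalised by the total energy*, which then behave as they do with a
  real MLIP.
* **Adapter point.** A real MLIP is attached by passing any function
  `(elements, coords) -> list(energy, forces)` as `ml_potential` to
  `build_system()`; forces must be the negative gradient of the returned
  energy (finite-difference testable, and tested here for the
  surrogate).

## Units and constants

Energies are kcal/mol, lengths Angstrom, times fs, masses amu, charges
elementary. All constants are derived from CODATA definitions at load
time: the Coulomb prefactor is 332.0637 kcal·Å/(mol·e²), the Boltzmann
constant 1.9872·10⁻³ kcal/(mol·K), and 1 kcal/mol = 4.184·10⁻⁴
amu·Å²/fs² exactly (`ke_coulomb()`, `kB_kcal()`, `kcal_per_mdunit()`).

## Dynamics

NVE propagation uses velocity Verlet; NVT uses the BAOAB splitting of
Langevin dynamics, which reduces exactly to velocity Verlet at zero
friction. Default time steps are 1 fs, or 2 fs when bonds to hydrogen
are constrained with SHAKE (tolerance 10⁻⁸ Å, 500-iteration cap, with a
RATTLE-style velocity projection). Initial velocities are
Maxwell-Boltzmann draws with centre-of-mass motion removed; the usual
pre-production protocol (`prepare_equilibrated_frame()`) is L-BFGS
minimisation on the analytic forces, thermalisation, a short
thermostatted equilibration and removal of the residual centre-of-mass
momentum that the thermostat injects.

`stability_diagnostics()` reports the NVE robustness metrics: the
centre-of-mass speed, translational energy ½M|v₍COM₎|², rotational
energy ½ωᵀIω from the angular momentum about the centre of mass, the
standard deviation of the total energy, and the **energy drift**,
measured as |least-squares slope of E(t)| × run length / |mean E|. The
regression deliberately separates secular drift from the bounded
symplectic fluctuation: for velocity Verlet the fluctuation amplitude is
an O(dt²) oscillation (reported separately as `energy_std`, and the
quantity checked to shrink ~4× when dt is halved), while a true drift
would accumulate linearly.

One practical caveat the test suite exploits: a fully *planar* molecule
cannot be rigidified by pairwise distance constraints (out-of-plane
motion changes no pair distance to first order, so the constraint
Jacobian is singular and SHAKE stalls). The toy-solute generator
therefore builds its chains in a three-dimensional gauche geometry.

## Thermodynamic integration with an indivisible ML potential

The alchemical parameter λ scales **only** the region-region coupling:
λ = 0 is the decoupled (gas-like) state, λ = 1 the fully coupled one.
The free energy of switching the coupling on is estimated per window by
the time average of the analytic ∂V/∂λ and integrated with quadrature
weights,

$$\Delta G_\text{coupling} = \sum_i w_i
  \left\langle \partial V_\text{coupling}/\partial\lambda \right\rangle_i .$$

The ML region's internal energy is *never* scaled. With an indivisible
evaluator any λ applied to the ML energy would inevitably perturb the
(invariant) bonded terms too, which is precisely the failure mode this
scheme avoids; the intra-ML λ-derivative is identically zero in both
phases. What that omission leaves out — the conformational
reorganisation of the solute between environments — is restored by a
correction term computed from the two endpoint ensembles,

$$\Delta G_\text{reorg} = \langle E_\text{ML}\rangle_\text{solvated}
  - \langle E_\text{ML}\rangle_\text{gas},
\qquad
\Delta G_\text{solvation} = \Delta G_\text{coupling} + \Delta G_\text{reorg},$$

the second equation holding as an exact identity on every `ti_result`.
The solvated ⟨E_ML⟩ is taken from the λ = 1 window (the fully coupled
ensemble is the physically solvated state); the gas ensemble is
generated with the ML potential alone at the same temperature. Both are
design choices the formalism leaves open, fixed here and stated with the
result. Sign convention: λ 0→1 = coupling ON, so ΔG_solvation is the
gas → water transfer free energy. With a *rigid* solute the two
ensembles have identical internal geometry and ΔG_reorg vanishes to
machine precision.

### Coupling forms

The λ-dependence of the coupling is configurable:

* `linear` — E(λ) = λ·E(1), so ∂V/∂λ = E(1). Simple, but in dense
  solvent the λ→0 endpoint lets solvent overlap the solute and the
  integrand diverges.
* `softcore` (default for solvation) — Beutler-style with α = 0.5 and a
  single power-1 λ prefactor: the LJ r⁶ term is shifted by
  α(1−λ)σ⁶ and the Coulomb distance by α(1−λ). Both forms give
  E(0) = 0 exactly and agree at λ = 1 to 10⁻¹⁰; ∂V/∂λ is analytic in
  both. Published ΔG values must state the form used.

Whether charges and LJ should be switched in one leg or staged is left
to the protocol (one λ by default; staging can be emulated with user
weights and per-leg systems).

### Quadrature

Default protocol: 11 evenly spaced windows with composite-trapezoid
weights (for λ = {0, ½, 1} these are {¼, ½, ¼}); Gauss-Legendre rules
are available when the windows are placed at the Gauss nodes, and
arbitrary user weights are accepted. Trapezoid is exact for linear
integrands; the harmonic-stiffness test in the acceptance suite checks
the computed ΔG against the composite-trapezoid error bound
h²·max|f″|/12.

### Uncertainties

Window means discard an equilibration fraction (default 20–30 %) and
carry a standard error corrected for serial correlation by block
averaging (~20 blocks; equivalently a statistical-inefficiency
inflation, floored at the i.i.d. SEM). Window SEMs propagate through
the quadrature as √(Σwᵢ²σᵢ²) and combine with the reorganisation SEM in
quadrature. No standard-state or volume corrections are applied.

### Oracles

Two independent estimators guard the implementation:

* `oracle_bar()` — Bennett acceptance ratio from forward/reverse work
  samples, solved by root finding, with Bennett's asymptotic variance;
  it degrades gracefully to one-sided exponential averaging and warns on
  poor overlap. `coupling_bar()` chains pairwise BAR solves across the
  TI windows by re-evaluating stored frames at neighbouring λ values.
* `oracle_exact()` — brute-force ΔG = −kT ln(Z₁/Z₀) for one- or
  two-dimensional potentials by adaptive quadrature;
  `ti_exact_windows()` gives noiseless per-window ⟨∂V/∂λ⟩ by the same
  route, isolating quadrature error from sampling error.

Agreement of sampled TI, BAR and the exact oracle within three combined
standard errors on harmonic and droplet systems is the package's core
correctness claim; nothing stronger is asserted.

### A known, deliberate limitation

Scaling the coupling down gradually produces intermediate states in
which solute and solvent remain partially correlated; the
reorganisation correction compensates the *omitted intra-ML
perturbation*, not any residual coupling-path effect. The package
exposes the per-window profile so users can inspect this; it does not
attempt to resolve it.

## End-point analyses

`kabsch_rmsd()` superposes each frame on a reference by the SVD-based
Kabsch algorithm before measuring deviation; `compute_bfactors()`
superposes to the mean structure (one refinement pass) and reports
B = (8π²/3)⟨|Δr|²⟩; `bfactor_correlation()` is the plain Pearson
coefficient. `endpoint_binding_energy()` implements a single-trajectory
end-point estimate: per-frame receptor-ligand Coulomb and LJ interaction
energies plus an implicit-solvent change from a Still-type pairwise
generalized Born model with a γ·SASA nonpolar term (γ = 0.00542
kcal/mol/Å², Shrake-Rupley point-count SASA, 1.4 Å probe). Effective
Born radii are taken directly from an editable per-element intrinsic
table (`inst/extdata/born_radii.csv`) with no pairwise descreening — a
simplification appropriate for the small solutes treated here, and one
that preserves the exact single-ion Born limit
−(k_e q²/2R)(1/ε_in − 1/ε_solv). No conformational-entropy term is
included. The estimator preserves the *shape* of end-point binding
workflows; it is not a claim about any production MM-PBSA protocol.

## Synthetic fixtures and what passing tests mean

All validation inputs are generated, seeded and parameter-free of
external data:

* `make_toy_solute(n)` — a 3-D gauche chain with harmonic bonds
  (300 kcal/mol/Å², 1.5 Å), angles (50 kcal/mol/rad², 109.47°), soft
  3-fold dihedrals (0.5 kcal/mol), seeded neutral partial charges
  (σ_q = 0.15 e) and LJ sites; built at the equilibrium of its own
  surrogate terms. The rigid variant carries the full pairwise distance
  constraint set of that geometry.
* `make_solvent_bath(n)` — a generic flexible triatomic LJ-plus-charge
  solvent (O-H 0.9572 Å / 450 kcal/mol/Å², H-O-H 104.52° /
  55 kcal/mol/rad², charges −0.834/+0.417, LJ on the heavy site). The
  parameters are water-like but make no claim of fidelity to any real
  water model; 33 molecules give the standard 99-atom MM droplet used
  throughout the stability tests. Molecules are placed by rejection
  sampling with a 1.5 Å minimum distance.
* `make_harmonic_ensemble()` — isotropic Gaussian wobble with exact
  B = 8π²σ²; `make_harmonic_1d()` — paired wells with
  ΔG = (k_BT/2)ln(k₁/k₀) in closed form.

Problem sizes are chosen for statistical convergence on a single CPU: a
~100-atom droplet for NVE stability (10,000 × 0.5 fs steps at 100 K — a
temperature at which an open-boundary droplet stays bound), a 5-atom
solute in 15 solvent molecules for the TI/BAR cross-check
(11 × 1500 × 1 fs windows), 3 × 10⁴-step windows for one-dimensional TI
and 10⁶ steps for the equipartition calibration.

These fixtures emulate the *mechanics* of solvated-ligand free-energy
calculations — region partitioning, coupling, reorganisation, estimator
statistics — not real chemistry: there is no hydrogen-bond network
directionality, no polarisation, no conformational multi-minima
landscape of drug-like molecules. A green suite therefore certifies the
algorithms and their statistical machinery, not hydration-free-energy
accuracy on real compounds, which requires a trained MLIP attached at
the adapter point.

## Numerical choices

* Nonbonded interactions have no cutoff by default (systems are small);
  with a periodic box, minimum-image convention applies. Conservation
  tests use open-boundary droplets because cutoff-free minimum-image
  forces are discontinuous at image switches.
* Cross LJ parameters by Lorentz-Berthelot combining on σ/ε recovered
  from the per-atom A/B coefficients; atoms with zero A or B contribute
  no LJ.
* Overlapping nonbonded pairs (r < 10⁻⁶ Å) are a hard error rather than
  a silent divergence.
* The softcore σ⁶ shift falls back to 1 Å⁶ for pairs lacking LJ
  parameters, keeping the Coulomb softening active.
* One-dimensional Langevin samplers scale dt and friction to the well
  frequency (ω·dt = 0.15, γ = ω): near-critical damping decorrelates
  positions quickly, keeping block-averaged SEMs honest; the residual
  O((ω dt)²) configurational bias is below the statistical errors used
  in any comparison.
* Angle forces guard against collinear geometries by clamping cos θ
  away from ±1; dihedral angles use the atan2 formulation, which is
  singularity-free away from collinear bond vectors.

## Limitations

Mechanical embedding only (no electrostatic embedding or ML-region
polarisation); no PME/Ewald; no link atoms; no barostat; no replica
exchange or MBAR (pairwise BAR is the validation oracle); no
relative-binding topology transformations; the GB model uses intrinsic
radii without descreening and a point-count SASA. The surrogate ML
potential is classical; conclusions about trained-MLIP accuracy are out
of scope by construction.
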