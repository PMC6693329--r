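---
title: "Mapping potential energy surfaces with augmented basin-hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping potential energy surfaces with augmented basin-hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhmap)
```

# The problem

The observable behaviour of a fluxional molecular system — which isomer
carries an IR spectrum, how an ion's collision cross section (CCS) drifts
with effective temperature — is governed by the ensemble of local minima on
its potential energy surface (PES), not by any single structure.
Basin-hopping (BH) coarse-grains the PES into exactly that ensemble: it
alternates random geometric perturbation, local minimization, and an
acceptance test, so that the surface is explored plateau by plateau.
`bhmap` implements the BH engine together with the analyses that make its
output usable: quantitative similarity between minima, hierarchical
clustering and 2D embedding of the minima library, interpolation of
intermediate structures, spectral-carrier ranking, and Boltzmann-weighted
CCS curves.

# The basin-hopping loop

One step of `run_bh()` is perturb → screen → minimize → accept → register.

* **Moves.** Resolved from the topology: chains receive uniform dihedral
  twists within ±`dihedral_step` (default 5°, preserving all bonded
  distances); designated moieties receive rigid rotations within
  ±`rigid_rot_step` (5°) about their body axes plus translations within
  ±`translation_step` (0.5 Å); atomic clusters with no topology get
  independent per-atom displacements. The defaults are the move ranges used
  for hydrogen-bonded dimer searches; for reduced-unit Lennard-Jones work we
  use 0.35 σ.
* **Screening.** Before spending a minimization, candidates with a
  nonbonded pair closer than `min_interatomic` (default 0.8 Å) or an atom
  farther than `interaction_radius` (15 Å) from the centre of mass are
  rejected and logged. Screened-out steps still consume the step budget, so
  `n_steps` is an honest cost measure.
* **Acceptance.** Two criteria: a minimum below the current global minimum
  E_low replaces it unconditionally; otherwise a Metropolis test against the
  current walker structure accepts with probability
  min(1, exp(−ΔE/`thermal_energy`)). `thermal_energy` is the k_BT of the
  statistical-accessibility window (≈0.43 eV corresponds to 5000 K).
* **Registration.** Every converged minimum is offered to the library, not
  only accepted ones: acceptance steers the walker, while the library is
  the map. A candidate is a *duplicate* only when it is close to a stored
  record in both energy (|ΔE| < `energy_tol`, default 10⁻⁵) and geometry
  (distance-matrix index < `similarity_tol`, default 50 Å); it is unique if
  it differs in either. For Lennard-Jones clusters in reduced units the
  energy criterion is the operative one, which also merges the
  permutational and mirror copies of a physical minimum — intended
  behaviour for a minima census.

The loop is a pure function of its config seed: two runs with the same
config produce identical logs and libraries.

# Similarity functions

Two complementary representations, both rotation- and
translation-invariant:

* **Distance matrix** (`distance_matrix()`, `dm_similarity()`): all
  interatomic distances; the index is the summed absolute difference over
  unique pairs, in Å. Memory grows quadratically with atom count, and the
  representation is *not* permutation-invariant, so relabelled structures
  need an atom mapping (below).
* **Mass-weighted vector** (`mass_weighted_vector()`,
  `cosine_distance()`): per-atom mass × distance to the centre of mass,
  compared by arccos of the normalized dot product divided by π. Linear
  scaling; with `sorted = TRUE` also permutation-invariant. The trade-off
  is weaker discrimination of highly symmetric structures (two different
  conformations can share the same sorted vector), so energies should be
  consulted alongside it.

Convention: within a single BH run atom identity is tracked, so unsorted
vectors and the identity mapping are the defaults there; across provenances
(different runs, external structures) use sorted vectors or the
element-constrained mapping.

**Atom mapping.** The mapping that minimizes the distance-matrix index over
element-preserving permutations is a hard combinatorial problem. `bhmap`
enumerates it exactly whenever the number of element-preserving
permutations is at most 5040 (e.g. any system up to 7 interchangeable
atoms), and otherwise uses a two-step heuristic: per-element rank-matching
of the scalar mass-weighted distances (the exact solution of that 1D
assignment), refined by element-preserving pair swaps to a local optimum.
The heuristic carries no global guarantee — on unrelated random structures
a swap-refined local optimum can sit well above the true minimum — which is
why small systems are enumerated. `dm_similarity(..., "assignment")`
additionally never exceeds the identity-mapping value.

# Clustering and embedding

`wpgma()` implements weighted pair-group averaging directly: at every
iteration the two nearest groups merge and the merged group's distance to
any other group is the arithmetic mean of its members' distances. Ties in
the nearest-pair search are broken by the lowest (i, j) index pair, making
the linkage deterministic and label-order invariant up to relabelling.
`ward()` delegates the classical Lance–Williams minimum-variance update to
`stats::hclust(method = "ward.D")` on the raw distance matrix — the
distance-matrix index is not exactly Euclidean, and the raw-matrix usage is
deliberate, matching how these indices are clustered in practice. Both
return hclust-compatible trees: `cut_groups()` (via `stats::cutree`),
`linkage_table()`, and `linkage_newick()` (via `ape`) operate on either.

`mds2d()` embeds a distance matrix in 2D by classical scaling
(eigendecomposition) refined with iterative stress majorization of the raw
squared-error stress Σ(δ_ij − d_ij)²; iteration stops when the relative
stress change falls below 10⁻¹². The reported stress is recomputed from the
returned coordinates, so it is self-consistent by construction. The seed
matters only if the classical start is degenerate and random jitter is
required.

# Interpolating intermediate geometries

Given minima A and B and λ ∈ (0, 1), the target distances
r̄_ij = λ D_A,ij + (1−λ) D_B,ij define an artificial force field of
harmonic pair terms with force constants ∝ 1/r̄_ij:
V = χ Σ_{i<j} (D_C,ij − r̄_ij)²/r̄_ij. `interpolate_ff()` minimizes V from
the Kabsch-superposed Cartesian blend λA + (1−λ)B (stage 1), then
re-minimizes the result on the real potential (stage 2), tagging the
record's provenance as `"interpolation"`. χ defaults to 1 (it only scales
the optimization); λ defaults to 0.5, the midpoint.

Notes on this construction:

* A blended distance matrix is generally *not* exactly realizable in 3D,
  so the stage-1 optimum can have V > 0; the report carries both the
  residual and the maximum entrywise deviation from r̄.
* A distance matrix determines a structure only up to reflection; both
  mirror realizations are accepted as valid interpolants.
* Orientation convention: λ = 1 reproduces A's distances, so an exact
  realization satisfies d(A,C) = (1−λ)·d(A,B) and d(B,C) = λ·d(A,B).
  `verify_eq_interp()` reports the deviations from this relation (at the
  midpoint the two orientation conventions coincide).

`mc_constrained_sample()` is the sampling alternative: a plain BH walk
whose acceptance additionally rejects minimized structures farther than a
radius from either endpoint, confining exploration to the lens between
them. With infinite radii it reduces exactly (same RNG stream) to plain BH.
`select_pairs()` chooses interpolation candidates as record pairs more
distant than a threshold, subsampled reproducibly;
`augment_library()` applies the two-stage interpolation across the selected
pairs and registers new minima with the same uniqueness thresholds as the
run — the library can only grow, and the best energy can only improve.
`ts_guess_export()` writes reactant/guess/product triples as 3-frame XYZ
for external synchronous-transit TS searches.

# The spectral pipeline

Computed stick spectra pass through: per-region frequency scaling (region
assignment by unscaled frequency; strays outside every region are dropped
with a warning), Lorentzian broadening, grid evaluation, per-region max
normalization, and concatenation. Choices worth stating:

* **Lorentzian convention**: unit peak height per line scaled by the line
  intensity, γ = FWHM/2. Since each region is subsequently max-normalized,
  only relative shape matters and the peak-height vs unit-area choice is
  immaterial downstream; peak-height is used.
* **Defaults**: regions 1000–1900 cm⁻¹ (scale 0.9679) and 3200–3800 cm⁻¹
  (scale 0.95) on a 2 cm⁻¹ grid, 15 cm⁻¹ FWHM — the standard
  fingerprint/hydride-stretch setup for hydrogen-bonded cluster ions. All
  are configurable per region.
* An "empty" region (no stick line inside its bounds) is marked, not an
  error; tails from neighbouring regions may still contribute intensity.
* Experimental spectra enter as already-digitized two-column tables and are
  linearly resampled onto the region grids; computed spectra are resampled
  onto the experiment's grid before comparison if needed.

`euclid()` compares intensity vectors on identical grids;
`scaled_similarity()` maps distances to scores 1 − (d − d_min)/max(d −
d_min), pinning the best candidate to exactly 1 and the worst to exactly 0
(the reading of the normalization that makes the worst candidate score 0);
an all-equal distance set has no defined scores and errors.
`rank_carriers()` composes the whole pipeline and sorts candidates by
score. IRMPD intensities are not linear-absorption intensities; the ranking
assumes relative band intensities are comparable across candidate isomers,
which is the standard working assumption and a documented caveat.

# Ensemble mobility

Relative Gibbs energies enter either analytically (ΔH, ΔS with
ΔG(T) = ΔH − TΔS) or as tables interpolated linearly in T (extrapolation is
refused). Populations use the gas constant R because the energies are
molar (kJ/mol): N_i = exp(−ΔG_rel,i/RT), normalized to fractions. The
crossover temperature of two conformers with analytic thermochemistry is
ΔΔH/ΔΔS, where their populations are exactly equal. `weighted_ccs_curve()`
forms Ω_B(T) = Σ f_i(T) Ω_i, bounded by the ensemble's min and max CCS; for
an ensemble whose extended conformers are entropy-favoured, Ω_B(T) rises
with temperature — the unfolding signature that underlies dynamic-CCS
behaviour in differential mobility.

`pa_ccs()` is a *projection approximation* stand-in: the orientationally
averaged projected area of the union of atom-centred disks (van der Waals
radius + probe radius), estimated by seeded Monte Carlo with a reported
standard error. It ignores long-range ion–neutral interactions and
scattering, so its absolute values are not comparable with
trajectory-method CCS calculations; it exists to exercise the ensemble
machinery on geometric input. `mason_schamp()` implements the standard
low-field mobility expression K = (3/16)(ze/N)·√(2π/(μ k_B T))/Ω with
1/μ = 1/m_ion + 1/m_gas, SI units internally.

# Synthetic generators and what they do (not) show

All generators are pure functions of their parameters and seed:

* `make_lj_cluster()` — uniform box placement with a 0.7 σ separation
  floor; the BH benchmark substrate.
* `make_torsion_chain()` — unit bonds, tetrahedral angles, random
  dihedrals, with full bond/dihedral topology for the move set.
* `make_difluoroethene_set()` — three idealized planar C₂H₂F₂ isomers
  (C=C 1.33 Å, C–F 1.35 Å, C–H 1.08 Å, 120° angles) for qualitative
  clustering checks; they are constructions, not optimized geometries, so
  quantitative distances differ from semiempirical ones. The published
  three-isomer cosine matrix itself ships in
  `inst/extdata/difluoroethene_cosine.tsv` for the exact worked example.
* `make_spectra_set()` — random stick spectra with one designated carrier
  whose processed spectrum, perturbed by multiplicative Gaussian intensity
  noise and re-normalized per region, becomes the "experiment".
* `make_two_state_ensemble()` — compact/extended pair with closed-form
  crossover (defaults: ΔH = 10.5 kJ/mol, ΔS = 25 J/mol/K → 420 K;
  CCS 148/160 Å²).

Passing tests on these fixtures demonstrates the algorithms' contracts —
determinism, invariances, planted-structure recovery, closed-form limits —
on landscapes whose answers are known. They do not emulate DFT-quality
energetics, real IR intensity physics, anharmonicity, or trajectory-method
CCS values, so agreement with real experimental data is a separate
validation a user must perform with their own model chemistry.

# Numerical choices

* Local minimization: L-BFGS-B with analytic gradients (all models pass a
  central-difference check at 10⁻⁵ relative), gradient max-norm tolerance
  10⁻⁶, iteration budget 2000 with restarts. Non-finite energies during
  minimization are capped, and a candidate that still fails the gradient
  test is logged as `minimization_failed` rather than registered.
* The torsional chain adds stiff harmonic bond and angle restraints
  (k = 100) to the cosine torsion series and soft-sphere repulsion.
  Unconstrained Cartesian minimization of a dihedral-only energy is
  ill-posed (bond and angle directions are flat); the restraints vanish
  identically on the unit-bond/tetrahedral manifold the generator produces,
  so on that manifold the energy is a function of dihedrals and nonbonded
  distances only, as intended.
* Atomic masses: most-abundant-isotope values to 4 decimals; the
  pseudo-element "X" (mass 1) serves reduced-unit models.
* WPGMA tie rule: lowest (i, j) lexicographic pair. Degenerate MDS starts
  fall back to seeded jitter. Mapping enumeration cap: 5040 permutations.
* Test and reference problem sizes were chosen as the smallest landscapes
  that still exhibit the phenomena: LJ7 for multi-start checks, LJ13
  (8 runs × 500 steps; 500-start global-minimum oracle, which recovers the
  icosahedral −44.326801 ε minimum) for the search-plus-interpolation
  study, 10-isomer spectra sets at 5% noise for carrier recovery, and
  4-atom chains with a six-fold torsion series for planted-intermediate
  interpolation.

# Known limitations

* No electronic-structure backends: the engine is model-potential based by
  design; real systems require coupling to an external optimizer.
* Compared structures must have equal atom counts; mixed-composition
  libraries are rejected.
* The distance-matrix index is not a metric in the strict sense for the
  mapped variant, and Ward on raw (non-Euclidean) distances inherits the
  usual caveats of that practice.
* BH is stochastic: no run guarantees the global minimum; confidence comes
  from seed-parallel consistency, which the tooling makes cheap to check.
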