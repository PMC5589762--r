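---
title: "Restraint-driven ensemble modelling of a chaperone-histone complex: methods"
author: "czbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-driven ensemble modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(czbkit)
```

# The scientific problem

Histone chaperones such as Chz1 hand H2A.Z-H2B dimers to chromatin
remodellers. Chz1 is intrinsically disordered: even bound to the histone
dimer it adopts no compact fold, instead wrapping around the dimer in an
extended, lasso-like conformation. A single NMR model under-represents
such a complex; the natural description is a conformational *ensemble*
consistent with the experimental NOE distance restraints. `czbkit`
implements the full computational workflow for building and interrogating
such an ensemble:

1. restraint preparation (aliphatic-proton remapping, bound padding),
2. replica-exchange Monte Carlo sampling of the chaperone chain under
   restraint, tether and excluded-volume potentials,
3. ensemble refinement by energy and restraint violation, with k-medoids
   centroid extraction,
4. interface quantification (per-residue heavy-atom contacts, buried
   solvent-accessible surface area), and
5. an in-silico point-mutation screen of the histone-side interface.

Every stage is testable offline against a synthetic-data generator that
emulates the geometry of the real system.

# Restraints and violations

An NOE restraint is an upper bound `d` on the distance between two atoms;
violations are one-sided, `max(0, r - d)`. Two preparation rules mirror
the treatment needed by force fields without explicit aliphatic
hydrogens:

* **Remapping**: a restraint endpoint naming a carbon-bound hydrogen is
  moved to that carbon and the bound grows by 1 Å *per remapped
  endpoint*, absorbing the extra bond length. Hydrogens on N/O/S (polar)
  stay. Methyl protons collapse onto one carbon; duplicated pairs merge,
  keeping the loosest bound (the conservative NOE convention).
* **Padding**: all bounds grow by 1 Å, absorbing the spread of the NOE
  signal. Padding is additive and flagged, so analyses can report both
  the modified and original-bound variants of any violation statistic
  (`padRestraints`, `meanEnsembleViolation`).

Because the NOE signal scales as `r^-6`, the effective distance of an
ensemble is `(mean_j r_j^-6)^(-1/6)` (`r6AverageDistance`). This mean is
dominated by the *shortest* distances: an ensemble that satisfies a
restraint transiently satisfies it in the r⁻⁶ sense. Two consequences are
deliberately reflected in the tests: the effective distance obeys the
power-mean inequality (never above the arithmetic mean, always between
the extremes), and mild coordinate noise produces *exactly zero* r⁻⁶
violation — the statistic only reacts to perturbations large enough that
even the closest approach breaks the bound. Per-snapshot filtering
therefore uses the plain per-structure mean violation, and the r⁻⁶
statistic is reserved for describing a final ensemble; conflating the two
would make the filter insensitive.

# Sampling

The sampler is replica-exchange Metropolis Monte Carlo over three energy
terms:

* **Two-well restraint potential**: zero inside
  `[lowerEdge, upper bound]`, a step `innerStep` below `lowerEdge`
  (default 1.8 Å, hard-contact distance), and a step plus *linear ramp*
  (`outerStep` per Å) above the bound. Stepped two-well forms are the
  convention in event-driven samplers, but pure steps give single-move
  Monte Carlo proposals no restoring gradient; the linear ramp preserves
  the stepped topology while restoring that signal.
* **Harmonic tethers**: `k |x - x_ref|²` per atom with `k = 0.4`
  kcal·mol⁻¹·atom⁻¹ on the histone backbone, read as the energy of a 1 Å
  displacement (no ½ factor, matching the per-atom unit).
* **Soft-sphere excluded volume**: `(σᵢⱼ - r)²` for heavy-atom pairs
  closer than `σᵢⱼ` = sum of element radii (C 1.7, N 1.55, O 1.52,
  S 1.8, P 1.8 Å). Pairs within one residue or between sequence-adjacent
  residues are excluded — those are bonded-geometry distances, always
  below σ, and are fixed by construction rather than scored.

Moves act on the flexible chaperone chain only: torsion pivots about
φ/ψ axes (rotating everything downstream, preserving bond geometry),
local crankshaft rotations between two CA atoms, and single-atom jiggles.
The histone core is held rigid; this realises the modelling intent (fixed
dimer, enhanced chaperone sampling) exactly rather than approximately,
and makes the tether-containment guarantee structural. The default
temperature ladder is the 16-value reduced-unit ladder 0.480…0.767
(roughly 240–383 K); nearest-neighbour exchanges alternate even/odd pairs
with acceptance `min(1, exp((1/T_i - 1/T_j)(E_i - E_j)))`. Each replica
owns an RNG stream seeded `seed + replica`, so changing the replica count
never reshuffles streams, and a fixed seed reproduces the trajectory
bit-for-bit.

The statistical mechanics is verified rather than assumed: a single
tethered particle reaches per-axis coordinate variance `T/(2k)` (the
Boltzmann closed form for `E = kx²`) within 5% over 10⁶ steps; Metropolis
acceptance at `ΔE = T` converges to `e⁻¹`; and a two-state ×
two-temperature exchange toy reproduces the analytic Boltzmann
occupancies.

This Monte Carlo engine is a desk-scale stand-in for event-driven
(discrete) molecular dynamics over the same restraint and tether
potentials; kinetic observables, event-driven integration and full
molecular-mechanics force fields are out of scope, and the nominal
~50 fs time unit of such engines is carried only as configuration
metadata.

# Refinement

Snapshots are filtered sequentially: keep the lowest `p`% by each named
energy annotation (default 50%, any externally computed potential can be
supplied as an annotation), then drop members whose per-structure mean
violation exceeds `violationMax` (default 0.5 Å). These defaults are exposed
configuration; no particular literature thresholds are implied. Tightening either criterion can only shrink the result
(tested), and the r⁻⁶ interface violation of the refined ensemble never
exceeds the unfiltered one.

Centroids come from PAM k-medoids (build + swap, `cluster::pam`) on a
pairwise RMSD matrix; the default RMSD selector superposes on chaperone
backbone because the tethered histones barely vary. PAM's build phase is
deterministic, so no seed enters; `k = 6` mirrors the number of
representative structures typically drawn from such ensembles.

# Interface analysis

A contact is a heavy-atom pair, one atom per group, within 6.0 Å
*inclusive* (the boundary case is pinned by a test). Per-residue counts
are averaged over the ensemble; the heat-map export writes them into the
PDB B-factor column plus a TSV. Buried surface area is
`SASA(A) + SASA(B) - SASA(AB)` with Shrake–Rupley SASA on a deterministic
golden-spiral point set (default 960 points, probe 1.4 Å); single-sphere
and fused-two-sphere cases match closed forms within 1%. Across an
ensemble the buried area is reported as mean ± SD, with the spread
statistic labelled explicitly as SD.

# Mutation screen

At each histone-side interface site, every standard amino acid except
proline, cysteine and the native residue is a candidate — 17
substitutions at a typical site (18 at a native cysteine, where only
proline and the native are excluded). Each ΔΔG run repacks four arms with
a fixed backbone: mutant and wild type, in the full complex and in the
dimer with the chaperone chain deleted (the unbound reference), and
combines them as

```
ΔΔG = (ΔG_complex,mut − ΔG_dimer,mut) − (ΔG_complex,wt − ΔG_dimer,wt)
```

so positive values are destabilising. Repacking is simulated-annealing
rotamer Monte Carlo (geometric schedule, default T = 5 → 0.1 over 200
sweeps; tests and the acceptance script use 40-sweep schedules on the
small benchmark systems) over a backbone-independent library built from
staggered χ values (−65°, 65°, 180°; ±90° for aromatic χ₂) with prior
weights entering the energy as −log w. The packing energy is a documented
surrogate — soft-sphere repulsion, distance-dependent-dielectric Coulomb
(332·q₁q₂/(4r²), unit charges on Lys/Arg/Asp/Glu termini, 10 Å cutoff)
and the rotamer prior. It supports *sign and rank* statements, verified
on a generator benchmark with planted ground truth; its absolute values
are not calibrated against any published kcal/mol scale, and reproducing
published per-mutation values is explicitly out of scope.

Mutant and wild-type arms share RNG seeds pairwise, so a wild-type
"mutation" cancels algebraically to exactly zero — a useful audit — while
`pairSeeds = FALSE` exposes the unpaired repack noise floor against which
the distal-site control is judged. Aggregates report mean and standard
error over all runs × centroids; run counts at the
hundreds-per-centroid scale of production repacking protocols are a
parameter, with desk-scale defaults.

# The synthetic generator, and what it does not show

`makeToyComplex` builds two compact coiled core chains stacked coaxially
(a cylindrical stand-in for the histone dimer) and wraps an extended
chain around them on an arc at a controlled clearance (default 4.2 Å)
covering a configurable fraction of the circumference (default 2/3, the
lasso geometry). Side chains come from idealised internal-coordinate
templates, with a small greedy rotamer choice keeping the reference
clash-free; a 0.02 Å seeded jitter distinguishes seeds without changing
geometry. `deriveTrueRestraints` picks cross-chain heavy-atom pairs
≤ 5 Å and sets bounds to the reference distance plus slack (0.5 Å), so
the reference violates nothing by construction. Decoy ensembles perturb
only the chaperone with Gaussian noise at labelled σ levels
(0.25/1.0/3.0 Å defaults); the ΔΔG benchmark plants one small interface
residue whose enlargement must clash with the wrap and one distal control
residue more than 12 Å from it.

Passing on these fixtures demonstrates the *mechanics*: restraint
bookkeeping, sampler thermodynamics, filter selectivity, geometric
analysis and sign recovery. It does not demonstrate force-field realism,
the energetics of real side-chain packing, or agreement with any
published per-complex number — real proteins have irregular surfaces,
correlated restraint networks and electrostatics the surrogate terms only
sketch.

# Numerical choices and degenerate inputs

* Problem sizes: tests and the acceptance script use 16–20-residue core
  chains (~250–330 atoms), 3 000–step × 4-replica sampling runs,
  100-member decoy mixtures and 5–160 repack runs per mutation; these are
  the package's chosen desk-scale study conditions.
* Alternate locations keep the highest occupancy (ties → altloc A);
  missing element columns fall back to the atom-name leading character.
* Superposition needs ≥ 3 non-collinear atoms on both structures and
  refuses degenerate selections; RMSD matrices are exactly symmetrised.
* Restraints with coincident atoms (r = 0) raise a singularity error in
  r⁻⁶ averaging rather than returning infinity.
* An all-members-removed filter is an error carrying per-criterion
  removal counts, not an empty ensemble.
* Wrap geometries whose arc spacing leaves the 3.0–4.2 Å band are
  generation errors: the generator refuses rather than silently bending
  bond geometry; at the default core size this makes wrap fractions
  below ~0.12 infeasible.
* k-medoid ties resolve to the lowest index via PAM's deterministic
  build order.

# Entry points

The exported functions are the interface; a typical session is the
pipeline in `scripts/acceptance.R`: `makeToyComplex` /
`readStructureModels` → `parseRestraints` (or `parseXplorRestraints`) →
`remapAliphatic` / `padRestraints` → `runSampling` → `filterEnsemble` →
`extractCentroids` → `averageContacts` / `ensembleBuriedSasa` →
`screenInterface`.
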