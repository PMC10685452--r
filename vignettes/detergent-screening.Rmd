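---
title: "Computational detergent screening: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational detergent screening: models, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detscreen)
```

## The screening problem

Membrane proteins depend on their lipid environment for structural
stability, and extracting one into detergent micelles requires a detergent
that does two different jobs at once. It must *invade* the phospholipid
bilayer — partition into the membrane so it can displace the lipids that
wrap the protein — and it must *stabilize* the extracted protein so the
native fold survives. A detergent that is excellent at one and poor at the
other solubilizes nothing useful. `detscreen` implements the trajectory
post-processing side of a simulation-based screen that scores a candidate
detergent panel on exactly these two axes and combines them into a single
rank order, together with a third, descriptive analysis: where on the
protein surface the detergent's hydrophilic head groups versus hydrophobic
tail groups make contact.

The package analyzes trajectories; it does not generate physical ones.
Its inputs are annotated structures and trajectories (multi-model PDB,
GRO, or a compact extended-XYZ dialect, plus a flat annotation file
labeling each molecular species as protein / lipid / detergent / solvent /
ion and each detergent atom as head or tail). Its seeded toy-dynamics
generators exist so that every statistic the package computes can be
validated against a closed-form expectation at desk scale.

## The three statistics

**Membrane invasion.** A detergent molecule is *in contact* with the
membrane in a frame when any of its heavy (non-hydrogen) atoms lies within
a cutoff — 0.6 nm by default — of any lipid heavy atom, with distances
computed under the minimum image convention in an orthorhombic periodic
box. The invasion statistic is the percentage of detergent molecules in
contact, averaged over an analysis window (by default the second half of
the trajectory, the usual production-averaging convention when no
equilibration point is specified). Two framings are provided because both
are used in practice: the per-system total
(`detergent_invasion_fraction()`) and the per-lipid profile
(`per_lipid_detergent_profile()`), which reports, for each lipid, the
time-averaged percentage of detergent molecules around it, ranked from
highest to lowest, with the mean and standard deviation over lipids as the
summary and error measure. A detergent near two lipids counts toward both;
no exclusive assignment is attempted, which is the simplest reading of
"detergent around each lipid". The contact boundary is closed (distance
equal to the cutoff counts), making exact-boundary cases deterministic.

**Structural stabilization.** Per-residue RMSF is computed after
least-squares rigid-body superposition of each frame onto a reference
(`residue_rmsf()`): the Kabsch algorithm with the determinant correction,
so reflections are never returned. The default fluctuation reference is
the iterated mean structure (fit, recompute the mean, refit, to a mean
shift below 1e-6 nm or 10 iterations); first-frame and external-frame
references are provided for workflows that define their own equilibrated
reference. The residue representative is the C-alpha atom when present,
otherwise the heavy-atom centroid of the residue; the fit selection
defaults to all protein heavy atoms and can be restricted to C-alphas or
disabled. Stabilization is scored as delta-RMSF (`delta_rmsf()`): the
residue-wise difference between the RMSF profile in the detergent
environment and a membrane-equilibrated reference profile, averaged over
residues. Lower average delta-RMSF means stronger stabilization.
Residue-wise subtraction is implemented (the scalar comparison is simply
its mean), and the averaging mask defaults to all residues — both choices
are interpretations, since screening reports rarely state them; masking to
a region is available through the region machinery.

**Regioselectivity.** `headtail_contact_map()` reports, per residue, the
fraction of frames in which at least one head-labeled (respectively
tail-labeled) detergent heavy atom is within the cutoff of the residue's
heavy atoms. Occupancy was chosen over raw contact counts deliberately:
it is robust to detergent copy number, and screening narratives describe
interaction patterns, not counts. The same 0.6 nm cutoff is used by
default (no separate protein-contact cutoff is standard), independently
configurable. `region_contact_summary()` aggregates the map over named
residue ranges (transmembrane helices, loops) supplied by the user, since
helix assignments are system-specific.

## Combining the axes

The two axes are combined by ranks, not raw values
(`classify_detergents()`, `rank_combined()`):

* *invader*: mean invasion percentage above a threshold, 45% by default —
  the natural boundary between the strong and weak groups in published
  screens of this design; a 25% annotation flags the clearly weak
  invaders without acting as a second gate.
* *stabilizer*: stability rank (1 = lowest average delta-RMSF, ties
  sharing mid-ranks) within the top half of the panel (rank at most
  ceiling(n/2)).
* *solubilizer* = both; *invader-only*, *stabilizer-only*, *poor*
  otherwise.
* combined order: `invasion_rank + stability_rank`, lower better, ties
  broken by the better stability rank and then by name.

The rank-sum is an artifact convention: screening reports combine the two
axes narratively, and a Borda-style rank sum with a stability tie-break is
the smallest formula that reproduces the qualitative conclusions such
reports reach (a mid-pack invader with mid-pack stability beating
detergents that are excellent on one axis and terrible on the other).
Because it depends only on ranks, the ordering is invariant under any
strictly monotone transformation of either metric — a property the test
suite checks. A z-score combination was considered and rejected for v1:
it adds a scale assumption without an anchor in how such screens are
reported.

## The synthetic generators and their closed forms

All three generators are seeded, byte-reproducible, and built so the
analyses have exact oracles.

**Slab partitioning** (`simulate_detergent_membrane()`): independent
detergent particles move by single-particle Metropolis Monte Carlo
(uniform displacement proposals in a cube of edge twice the step size) in
a square-well potential that is -epsilon (in kT) inside a slab of width
`h` and zero outside, periodic in all axes. Metropolis moves were chosen
over Langevin dynamics precisely because the stationary distribution is
exact, giving the closed form

\[ f_\mathrm{eq} = \frac{h\,e^{\varepsilon}}{h\,e^{\varepsilon} + (L_z - h)} \]

for the equilibrium fraction of particles inside the slab
(`slab_occupancy_expected()`). Lipid pseudo-atoms are static, placed on
two square leaflet grids at the slab quarter-planes; the exact placement
is arbitrary and irrelevant to the closed form. Detergent particles are
single-site: the invasion statistic is per-molecule, so multi-site realism
adds nothing to a correctness test.

For the invasion statistic to *track* the slab occupancy, the lipid
shells must tile the slab densely relative to the cutoff: with leaflet
planes at ±h/4 and grid spacing s, every point of the slab is within the
cutoff `c` of a lipid when \((h/4)^2 + s^2/2 \le c^2\). The pipeline
defaults (box 12 nm, slab width 1.6 nm, 800 lipid sites, cutoff 0.6 nm)
satisfy this; the contact region then overshoots the slab by a thin
margin, so measured invasion sits slightly above `f_eq` — visibly so for
weakly partitioning species, which is the expected geometric inflation,
not an estimator bias.

**Residue fluctuations** (`simulate_protein_fluctuations()`): each
coordinate of each residue pseudo-atom follows a discrete
Ornstein-Uhlenbeck update with autoregression `a = exp(-1/tau)` and
stationary per-coordinate standard deviation sigma_i, initialized from
the stationary law. The expected RMSF of residue i is exactly
`sigma_i * sqrt(3)`, and the lag-1 autocorrelation is `a` — both are
asserted by the tests. Inflating sigma by a per-detergent factor plants a
known stabilization ordering for end-to-end tests.

**Head/tail placement** (`place_regio_detergents()`): per frame, each
head (tail) particle selects a residue range with probability equal to
that range's head (tail) propensity; when the propensities sum to less
than one the remaining mass places the particle in bulk solvent away from
the protein (propensities summing to more than one are normalized). A
residue is drawn uniformly within the chosen range and the particle is
placed inside the contact distance, so regional contact shares are
binomial with known expectation. `n_detergent_particles` counts particles
*per role*. Residues should be spaced more than twice the contact
distance apart so contacts are unambiguous; the pipeline uses a straight
line with 2.5x spacing.

**What the generators do not emulate.** No force fields, no
electrostatics, no detergent–detergent interactions, no micellization, no
protein–detergent coupling (the protein model fluctuates independently of
the membrane model). Passing tests therefore demonstrate that the
*estimators* are correct — contact counting, superposition, RMSF
arithmetic, rank aggregation — not that any particular real detergent
invades or stabilizes. Percentages and delta-RMSF values comparable to
published all-atom screens require microsecond-scale MD of 40k+ atom
systems and are out of scope at desk scale; the default panel's
affinities and sigma factors are planted ground truth chosen once to
emulate the qualitative two-group pattern such screens report.

## Equilibration checks

Screening runs are compared only after an equilibration check mirroring
common practice: `checkpoint_convergence()` evaluates a metric (e.g. the
invasion series) at a handful of checkpoint times — the value at
checkpoint t is the mean over the interval since the previous checkpoint —
and declares equilibration when the last `k_last = 3` checkpoint values
agree within a tolerance. `rmsf_convergence()` does the analogous thing
for RMSF profiles computed on growing windows, comparing successive
profiles by their maximum absolute residue difference. Checkpoint times
are inputs, not guesses: published screens state their own checkpoint
schedules, and those numbers belong to the workflow, not the library.

## Numerical and design choices

* **Units**: nm and ps everywhere inside; Angstroms only at the PDB
  boundary. Only orthorhombic boxes are supported (triclinic input errors
  explicitly); cutoffs must stay below half the smallest box extent or
  the minimum image is ambiguous, and the package refuses to guess.
* **Cell list**: the neighbor search bins atoms into cells of edge at
  least the cutoff (`floor(L / cutoff)` cells per axis) and scans the 27
  neighboring cells; with fewer than three cells per axis the wrapped
  neighborhood degenerates to all cells, which remains correct because
  every pair distance is computed with the explicit minimum-image
  formula. Equality with the 27-image all-pairs brute force is asserted
  on randomized instances, including unwrapped input coordinates.
* **Heavy-atom rule**: element not H/D; when a format carries no element
  column, the first alphabetic character of the atom name decides, and
  generator atoms are named so that this fallback round-trips.
* **Molecule definition**: a contiguous run of one `molecule_id`
  (protein chains are one molecule; every non-protein residue is its
  own). No bond perception.
* **Kabsch degeneracy**: fewer than three points, or a covariance whose
  second singular value vanishes (collinear/coincident points), is an
  error rather than an arbitrary answer.
* **Heavy atoms on both sides** of the invasion contact (detergent as
  well as lipid) by default, configurable — reports of this design rarely
  state the detergent-side convention.
* **Molecule counting**, not atom counting, for invasion percentages
  (matching the "percentage of total detergent molecules" phrasing);
  atom-side granularity would change the statistic's meaning.
* **Seeding**: one master integer seed; every stream is derived from it
  by `derive_seeds()` (a seeded draw of sub-seeds), so a pipeline run is
  reproducible byte-for-byte from `--seed` alone.

## Problem sizes used in validation

The test-suite and acceptance-script sizes are chosen as the smallest
instances with unambiguous statistical power: 100 randomized neighbor-
search instances of up to 500 atoms; 20-seed replicates of 3000-sweep,
64-particle slab runs for the occupancy closed form (block-averaged
standard errors, three-sigma bands); 20000-frame OU runs for RMSF
recovery (per-residue error bounded by 5%, Spearman rank agreement with
the planted sigmas at least 0.99); 5000 frames for the planted 0.8/0.2
regioselectivity split (binomial three-sigma band); and a four-detergent
end-to-end pipeline (360 lipid sites, 60 particles, 40 residues) run
twice from one config to assert byte-identical reports.

## Known limitations

* Readers cover multi-model PDB, GRO, and the extended-XYZ dialect;
  compressed MD formats (XTC/DCD) are future work.
* The PDB writer truncates species names to the three-character residue
  field of the format; round-tripping full species labels requires the
  extended-XYZ dialect, whose name tokens carry species, molecule and
  residue identity.
* The regioselectivity occupancy is an operationalization: screening
  figures of head/tail contacts rarely define a statistic, and outputs
  label it as occupancy for that reason.
* Neither axis predicts enzymatic activity retention — the biochemical
  half of any real screen remains indispensable — and the package
  deliberately stops at the two-axis logic rather than predicting
  function.
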