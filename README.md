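# detscreen

Computational detergent screening for membrane protein solubilization —
an R toolkit for the trajectory post-processing side of simulation-based
detergent screens.

## The problem

Extracting an integral membrane protein from its bilayer requires a
detergent that can do two things at once: **invade** the phospholipid
membrane (so it can displace the lipids wrapping the protein) and
**stabilize** the extracted protein's fold (so the solubilized enzyme is
still worth having). Screening detergents empirically consumes large
amounts of scarce membrane protein; a simulation-based pre-screen scores
a candidate panel on both axes first, so only the most promising
detergents go into wet-lab trials.

`detscreen` implements the analysis layer of such a screen, for
structural bioinformaticians and simulation groups who already produce
trajectories:

* **Membrane invasion** — the percentage of detergent molecules with any
  heavy atom within a cutoff (default 0.6 nm) of any lipid heavy atom,
  under the minimum image convention, per frame and time-averaged
  (`detergent_invasion_fraction()`), plus the per-lipid ranked profile
  (`per_lipid_detergent_profile()`).
* **Structural stabilization** — per-residue RMSF after reflection-free
  Kabsch superposition (`residue_rmsf()`), differenced against a
  membrane-equilibrated reference profile:
  ΔRMSF_i = RMSF_i(detergent) − RMSF_i(membrane), summarized by its
  residue average (`delta_rmsf()`); lower is more stabilizing.
* **Regioselectivity** — per-residue contact occupancy of detergent
  hydrophilic head groups vs hydrophobic tail groups
  (`headtail_contact_map()`, `region_contact_summary()`).
* **Two-axis ranking** — invader iff invasion % > 45; stabilizer iff
  stability rank ≤ ⌈n/2⌉; *solubilizer* = both; combined order by the
  tie-broken rank sum `invasion_rank + stability_rank`
  (`classify_detergents()`, `rank_combined()`).
* **I/O & geometry** — multi-model PDB, GRO and an extended-XYZ dialect
  with a flat species/role annotation format; cell-list neighbor search
  on orthorhombic periodic boxes.
* **Seeded toy-dynamics generators** with closed-form expectations
  (Metropolis slab partitioning, Ornstein–Uhlenbeck residue
  fluctuations, propensity-driven head/tail placement), so every
  statistic is testable against an exact oracle.

The methods vignette (`vignettes/detergent-screening.Rmd`) documents the
models, assumptions, defaults and limitations in detail.

## Worked example

Simulate a detergent/membrane system with a known partitioning affinity,
measure invasion, score stabilization against a membrane reference, and
rank a panel:

```r
library(detscreen)

## membrane leg: slab partitioning with affinity epsilon = 2 kT
tr <- simulate_detergent_membrane(box = 12, slab_halfwidth = 0.8,
  n_lipids = 800, n_detergents = 240, epsilon = 2.0,
  step_size = 1.0, n_steps = 4000, sample_every = 20, seed = 11,
  species = "MEGA-9")
detergent_invasion_fraction(tr, cutoff = 0.6)
#> invasion: 54.80% +/- 3.25% of detergent molecules within 0.60 nm of lipid (100 frames)
slab_occupancy_expected(2.0, 1.6, 12)   # closed-form slab occupancy
#> [1] 0.532
```

The measured invasion (54.8%) sits just above the closed-form occupancy
(53.2%), as expected: the contact shell of the lipid leaflets slightly
overshoots the slab.

```r
## protein leg: OU fluctuations, detergent environment vs membrane reference
ref <- cbind(2 * cos(1:60), 2 * sin(1:60), 0.1 * (1:60))
prot_det <- simulate_protein_fluctuations(ref, 0.08 * 1.3, tau = 5,
                                          n_frames = 2000, seed = 12)
prot_mem <- simulate_protein_fluctuations(ref, 0.08, tau = 5,
                                          n_frames = 2000, seed = 13)
delta_rmsf(residue_rmsf(prot_det, label = "MEGA-9"),
           residue_rmsf(prot_mem, label = "membrane"))
#> delta-RMSF [MEGA-9]: average 0.0412 nm over 60 residues
```

A 30% inflation of the fluctuation amplitudes over a 0.08 nm baseline
yields an average ΔRMSF of +0.041 nm — close to the stationary
expectation 0.3 × 0.08 × √3 ≈ 0.042 nm.

```r
## two-axis ranking of a screened panel
scores <- data.frame(
  name = c("DDM", "BOG", "MEGA-9", "LMNG", "FOS-16", "GDN", "FOS-12", "CHAPS"),
  invasion_mean = c(62, 55, 50, 47, 22, 18, 15, 12),
  avg_delta_rmsf = c(0.080, 0.050, 0.030, 0.031, 0.015, 0.060, 0.012, 0.010))
rank_combined(scores, invasion_threshold = 45)[, c("name", "combined_score", "class")]
#>     name combined_score           class
#> 1 MEGA-9              7     solubilizer
#> 2 FOS-16              8 stabilizer-only
#> 3    BOG              8    invader-only
#> 4  CHAPS              9 stabilizer-only
#> 5 FOS-12              9 stabilizer-only
#> 6   LMNG              9    invader-only
#> 7    DDM              9    invader-only
#> 8    GDN             13            poor
```

MEGA-9 is the only detergent that clears both gates (invasion above 45%
*and* a top-half stability rank), so it is the panel's sole solubilizer
and ranks first; FOS-16 edges BOG on the rank-sum tie through its better
stability rank. Strong invaders with poor stabilization (DDM) and strong
stabilizers that never enter the membrane (CHAPS, FOS-12) populate the
middle of the order.

The full pipeline — generators → all analyses → classification → report
files (summary CSV, per-analysis CSVs, run manifest JSON, text summary) —
runs from one flat config file and one seed, byte-reproducibly:

```r
run_pipeline("config.toml", out_dir = "screen_out", seed = 42)
```

A thin command-line wrapper with `run` / `invasion` / `stability` /
`regio` / `rank` subcommands is installed at
`inst/scripts/detscreen-cli.R`.

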