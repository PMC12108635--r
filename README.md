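# scfvfcdyn

Quantitative analysis of rigid-body domain motion in scFv-Fc antibodies —
bivalent fusions of a single-chain variable fragment (VH + VL joined by a
flexible linker) to an IgG1 hinge–Fc stalk. The hinge and linkers make the
two antigen-binding arms highly mobile; this package turns multi-frame
structural ensembles of such molecules into interpretable motion metrics,
and pairs them with the standard wet-lab characterization fits (thermal
shift, cell binding). It is written for structural bioinformaticians and
antibody engineers post-processing simulation or model ensembles.

## What it computes

All arm-motion metrics live in a **pivot/center framework**. Per
conformation, the pivot *p* is the midpoint of the two N-terminal Fc anchor
residues, and each subunit (scFv1, scFv2, Fc1, Fc2) gets a center point
*c*, the mean of its heavy-atom coordinates. The package reports:

* inter-subunit angles `θ = arccos( û_xy · v̂_xy )` between the XY-plane
  projections of center-minus-pivot vectors (degrees, unsigned, [0, 180]);
* contraction toward the pivot, `100 · (d_start − d_end) / d_start` with
  `d = ‖c − p‖` (positive = moved inward, negative = extension);
* signed z-displacement `(c_z − p_z)_end − (c_z − p_z)_start`;
* trajectory statistics after Kabsch alignment: RMSD and per-domain RMSD
  series (global-frame or per-domain refit), per-residue RMSF about the
  time-mean, radius of gyration `Rg = sqrt(Σ m_i ‖r_i − r̄‖² / Σ m_i)`, the
  medoid representative frame (minimal mean pairwise superposed RMSD), and
  the structurally closest frame to any query frame outside a temporal
  exclusion window, flagged against a 10 Å superposition-quality cutoff;
* interchain hydrogen bonds (≤ 3.5 Å donor–acceptor, ≥ 120° with explicit
  hydrogens), salt bridges (basic N to acidic O ≤ 4.0 Å), and group–group
  energies from a transparent stand-in potential
  `E = Σ [332.0636 q_i q_j / (4 r²) + ε_ij((R_ij/r)¹² − 2(R_ij/r)⁶)]`
  used only for percent-change bookkeeping between conformations;
* binding-site conservation: each arm's Fv aligned onto a reference Fv with
  overall and per-CDR-loop Cα RMSD against a 2 Å threshold;
* assay fits: melting temperature as the dominant interior extremum of
  |dF/dT| from Savitzky–Golay-smoothed melt curves, one-site saturation
  binding `Y = Bmax·X/(KD + X)`, and the four-parameter logistic
  `Y = Bottom + (Top − Bottom)/(1 + (EC50/X)^h)`.

A synthetic-data module generates every input with known ground truth:
Y-shaped toy scFv-Fc builds with exact requested angles, scripted
rigid-body trajectories (contraction, z-pitch, arm rotation, thermal
jitter), two-state melt curves, and 12-point threefold-dilution titrations.

## Worked example

Build a toy scFv-Fc at the canonical starting geometry, script a
compaction (scFv1 contracts to 53.3% of its pivot distance, scFv2 shifts
+37 Å in z) with 0.1 Å jitter, and measure it:

```r
library(scfvfcdyn)

tb <- build_toy_scfvfc(toy_build_config())
sc <- motion_script(list(
  motion_directive("scFv1", c(1, 40), contraction = 0.533),
  motion_directive("scFv2", c(1, 40), dz = 37)), jitter_sd = 0.1, seed = 42)
traj <- simulate_trajectory(tb$structure, tb$map, sc, 40, interp = tb$interp)

g_start <- geometry_summary(frame_structure(traj, 1), tb$map)
g_start
#> GeometrySummary ('toy-scFv-Fc[frame 1]')
#>   pivot (A): 0.09 0.02 -0.14
#>   angle scFv1-Fc1        105.4 deg
#>   angle scFv2-Fc2        151.3 deg
#>   angle scFv1-scFv2       67.1 deg
#>   scFv1    pivot dist   44.73 A   z-offset  +20.14 A
#>   scFv2    pivot dist   44.69 A   z-offset  +20.13 A
#>   Fc1      pivot dist   25.30 A   z-offset  -17.86 A
#>   Fc2      pivot dist   25.42 A   z-offset  -17.89 A

comparison_summary(g_start, geometry_summary(frame_structure(traj, 40), tb$map))
#> ComparisonSummary: 'toy-scFv-Fc[frame 1]' -> 'toy-scFv-Fc[frame 40]'
#>   scFv1    contraction  +46.40 %   z-displacement   -9.42 A
#>   scFv2    contraction  -56.06 %   z-displacement  +36.94 A
#>   Fc1      contraction   -0.50 %   z-displacement   -0.06 A
#>   Fc2      contraction   +0.17 %   z-displacement   -0.06 A
#>   angle scFv1-Fc1      change   -1.01 deg
#>   angle scFv2-Fc2      change   -0.76 deg
#>   angle scFv1-scFv2    change   -0.45 deg
```

Reading the jittered recovery: the starting angles sit at the requested
67°/105°/151°; scFv1's measured contraction (46.4%) matches the scripted
`100 × (1 − 0.533) = 46.7%` to within the jitter, and its z-offset falls
as the contraction scales the whole center–pivot vector; scFv2's +37 Å
z-shift is recovered as +36.9 Å and, because it lengthens the pivot
distance, reads as a −56% "contraction", i.e. an extension. The Fc stalk
stays put.

The assay side, with curves generated at known parameters:

```r
tm_from_melt(generate_melt_curve(60.6, noise_sd = 290, replicates = 3, seed = 1))
#> Tm = 60.57 +/- 0.17 degC (3 replicates)

fit_saturation_binding(generate_titration("saturation",
  list(kd = 12, bmax = 2921012), noise_cv = 0.03, replicates = 3, seed = 1))
#> One-site saturation fit: KD = 11.7 nM (SE 0.32), Bmax = 2.884e+06 (SE 1.9e+04)
#>   residual SD 3.82e+04
```

## The analysis workflow

`analysis/01_simulate.R` … `05_assays.R` run the full study on synthetic
systems: build and script three construct-like trajectories (writing bulky
intermediates under `scratch/`, expected values under `results/`), recover
the scripted geometry from the start-vs-representative comparison, report
interchain contacts and stand-in energies, check binding-site conservation,
and fit melt curves and titrations. Each script prints what it found and
writes tidy CSV tables under `results/`. Run them in order from the
repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

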