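---
title: "Quantifying scFv-Fc domain motion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scFv-Fc domain motion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfvfcdyn)
```

## The problem

An scFv-Fc is a homodimeric antibody format: two single-chain variable
fragments (each a VH and a VL domain joined by a flexible peptide linker)
fused through a hinge to an IgG1 Fc stalk. The hinge and linkers make the
two antigen-binding arms highly mobile, and the question this package
addresses is how to *quantify* that mobility from a multi-frame structural
ensemble: how far each arm swings, contracts toward the molecular core, or
pitches along the vertical axis, whether new inter-arm contacts form, and
whether the antigen-binding site itself stays intact while the arms
reorganize. Companion assay analyses (thermal-shift melting temperatures
and cell-binding titration fits) cover the experimental side of the same
characterization.

## The pivot/center angular framework

All arm-motion metrics are defined relative to two kinds of reference
points computed per conformation:

* the **pivot point** — the midpoint of the two N-terminal Fc anchor
  residues (one per Fc chain, P238 in the IgG1 numbering of the antibody
  application), each anchor located at the mean of its residue's atoms;
* a **center point** per subunit — the unweighted mean of the subunit's
  heavy-atom coordinates (an option restricts to alpha-carbons).

From these, three per-conformation quantities:

* `xy_angle(a, b, pivot)` — the unsigned angle between the XY-plane
  projections of the two center-minus-pivot vectors, in degrees within
  [0, 180]. Angles are unsigned because no rotational sense is defined for
  the molecule; the XY-plane is the plane of the alignment reference, fixed
  by `align_frames()`.
* pivot distance — by default the full 3-D distance from pivot to center.
  Whether arm "contraction" should use 3-D or XY-projected distances is
  genuinely open; we default to 3-D (the more conservative choice, since a
  vertical shift then counts against contraction) and expose
  `xy_distances = TRUE` in `geometry_summary()` as the alternative
  convention.
* z-offset — center z minus pivot z, signed, with +z simply the third
  coordinate of the alignment reference. No physical "up" exists for a
  molecule in solution; the sign convention is whatever the reference
  structure's frame provides, and comparisons are only meaningful between
  conformations aligned to the same reference.

Between two conformations, `comparison_summary()` reports per subunit the
contraction percentage `100 * (d_start - d_end) / d_start` (positive =
moved toward the pivot, negative = extension) and the z-displacement
`(z_center - z_pivot)_end - (z_center - z_pivot)_start`. Contraction and
angles are invariant under any rigid transform of a whole conformation
(pivot and centers move together); z-displacement is not, which is why
alignment to a common reference comes first.

## Trajectory statistics

`align_frames()` superposes every frame onto a reference by a Kabsch fit on
a selection (alpha-carbons by default), implemented via the singular value
decomposition with the usual reflection correction so the returned rotation
is proper (determinant +1); fewer than three points or a collinear point
set is a hard error. On top of the aligned trajectory:

* `rmsd_series()` — per-frame RMSD over a selection, without per-frame
  re-fitting (the global alignment is the fit);
* `domain_rmsd()` — per-subunit series in two modes: `"global-frame"`
  (subunit measured in the globally aligned frame, so rigid-body arm motion
  contributes) and `"refit"` (subunit superposed onto its reference copy
  first, leaving only internal deformation);
* `rmsf()` — per-residue root-mean-square fluctuation about the
  **time-mean** structure, not the reference — the common convention, and
  the one under which isotropic jitter of standard deviation sigma per axis
  converges to sigma * sqrt(3);
* `radius_of_gyration()` — mass-weighted by default, with masses from a
  small built-in element table (an unknown element gets 12.0 a.m.u. with a
  warning rather than an error, since toy systems may carry generic beads);
* `centroid_frame()` — the representative conformation, defined as the
  medoid under mean pairwise superposed RMSD. Single-cluster trajectory
  clustering in the MD engine that motivated this analysis is proprietary
  and unpublished; the medoid is the standard transparent surrogate for a
  one-cluster representative. Ties break to the lowest frame index.
* `closest_frame()` — the frame outside an exclusion window around a query
  frame with minimal superposed RMSD to it. The default window is 10% of
  the frame count on each side, so the "closest" frame is temporally
  distinct from the query rather than its immediate neighbour. The result
  carries a flag against a configurable 10 Angstrom quality threshold, the
  conventional cut-off for judging superpositions of two large predicted
  structures.

## Interchain contacts and the stand-in potential

Hydrogen bonds use geometric criteria: a donor-capable N/O in one group and
an acceptor-capable N/O in the other within 3.5 Angstrom, plus a
donor-hydrogen-acceptor angle of at least 120 degrees when explicit
hydrogens are present; heavy-atom-only models fall back to the distance
criterion alone. Salt bridges pair basic nitrogens (Lys NZ, Arg
NE/NH1/NH2, His ND1/NE2) with acidic oxygens (Asp OD1/OD2, Glu OE1/OE2,
C-terminal OXT) within 4.0 Angstrom. Both cutoffs are configurable; the
defaults are the common textbook values.

Group-group energies use a deliberately transparent **stand-in potential**:
Coulomb with a distance-dependent dielectric eps(r) = 4r plus a 12-6
Lennard-Jones term, parameters from a small built-in table
(CHARMM-flavoured magnitudes, keyed by residue:atom with an atom-name
fallback), 12 Angstrom cutoff, no periodicity. This is not a calibrated
force field and is labelled as such in every report; its purpose is to make
conformation-to-conformation *percent changes* well defined and fully
reproducible. Percent changes are computed on magnitudes —
`100 * (|e_end| - |e_start|) / |e_start|` — so that a strengthening
attraction reads as a positive "increase", the convention in which
attractive interactions are said to grow; a zero starting energy makes the
ratio undefined and is reported as NA with a warning.

## Binding-site conservation

`extract_fv()` takes one arm's VH + VL residues (linker excluded, mirroring
the convention of deleting constant domains before variable-domain
alignment), and `align_fv()` performs a Kabsch fit on mapped
alpha-carbons. The residue mapping is explicit rather than
sequence-derived: synthetic systems have no meaningful sequence, and for
real antibodies a 1:1 residue map (or the identity mapping for
self-reference) is supplied by the user, which also sidesteps the choice of
CDR numbering scheme — loop ranges are user-supplied in the domain map.
Per-CDR RMSDs are measured in the framework-fitted frame without per-loop
refitting, so a loop displaced relative to its framework is visible as
such; note that the global fit absorbs part of any localized displacement,
so a loop rigidly shifted by x Angstrom reads somewhat below x. The
conservation flag compares overall RMSD to a 2 Angstrom threshold by
default.

## Assay analyses

**Melting temperatures.** `tm_from_melt()` smooths each replicate with a
local-quadratic (Savitzky-Golay) filter (window 5 points), differentiates
by central differences, and takes the temperature of the dominant interior
extremum of |dF/dT|. Using the absolute derivative makes the estimator
correct under either sign convention of the derivative plot (dye-based
unfolding curves rise through the transition, so the derivative's sign
depends on plotting convention). The peak is refined by a least-squares
quadratic over a window of 8 grid points on each side of the argmax — wide
enough to average grid noise, narrow enough that the transition peak is
still locally quadratic; on a peak symmetric about a grid point the vertex
is that grid point exactly. An extremum on the grid boundary means no
interior transition and is an error, as is a flat curve. The estimate is
invariant under affine rescaling of the fluorescence.

**Binding fits.** `fit_saturation_binding()` fits Y = Bmax X / (KD + X) and
`fit_ec50()` fits the four-parameter logistic
Y = Bottom + (Top - Bottom) / (1 + (EC50/X)^h) with free Hill slope — the
standard model pair in the curve-fitting software this kind of assay is
usually analyzed with. Both use Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`) with positivity bounds, unweighted loss, and
replicates stacked and fitted jointly rather than averaged first (averaging
would discard the replicate scatter the standard errors are computed from).
Initialization: Bmax at the maximal signal, KD/EC50 at the concentration
nearest half-maximal signal, Hill slope 1. With h = 1 and Bottom = 0 the
logistic reduces algebraically to the saturation model with EC50 = KD,
which the test suite uses as a consistency identity. A titration whose top
concentration is below the fitted KD is flagged as non-saturating.

## The synthetic-data generator

`build_toy_scfvfc()` places six compact pseudo-domain clouds (VH and VL per
arm, two Fc domains) plus linker and hinge beads. The defaults encode the
starting conditions of the antibody application: 67 degrees between the two
arms and 105 / 151 degrees between each arm and its Fc chain, arm length 40
Angstrom, Fc radius 18 Angstrom, 40 atoms per domain, domain radius 3
Angstrom — magnitudes chosen to match a ~110-120 kDa scFv-Fc at one bead
per residue. Placement is exact by construction: the two single-atom anchor
residues sit symmetrically about the origin (so the pivot is exact), and
each subunit cloud is rigidly translated so its atom-mean lands on the
requested azimuth ray, making requested angles correct to machine precision
rather than approximately.

`simulate_trajectory()` applies per-subunit rigid transforms — rotation
about the pivot's z-axis, scaling of the center's pivot distance
(contraction), z-translation — with linear progress over each directive's
frame interval, recomputed from the start coordinates each frame. Linker
and hinge beads are then re-placed at their stored fractional positions
between their flanking anchors (domain centers or the Fc anchor), which
reproduces the start coordinates exactly under an empty script and keeps
the beads physically between their flanking domains when VH and VL move
independently. Isotropic Gaussian jitter is added last. All generators are
pure functions of (configuration, seed), restore the caller's RNG state,
and produce bit-identical output under a fixed seed.

What the generator deliberately does **not** emulate: real protein folds
(domains are random clouds — sufficient because every metric under test is
geometric), solvent and periodic boxes, force-field dynamics, correlated
thermal motion, or sequence realism. Passing tests therefore demonstrate
that the *metrics* are correct on inputs with known ground truth, not that
any particular biological system behaves a given way. Note one composition
effect that is real, not an artifact: when a single subunit combines a
contraction factor with a z-shift, the measured 3-D contraction differs
from 100 * (1 - factor), because the z-shift re-lengthens the pivot
distance; the stage-1 analysis script writes the exactly composed expected
values for this reason.

## Numerical choices and degenerate inputs

* Kabsch: SVD route, reflection corrected; < 3 points or collinear sets
  error out. The test suite checks the minimized RMSD against a
  multi-start rotation-grid search and an independent library routine.
* Angles: arccos of a clamped normalized dot product; zero-length XY
  projections (a center vertically above the pivot) raise an "undefined
  angle" error rather than returning an arbitrary value.
* Contraction requires a positive starting distance; percent change of a
  zero starting energy is NA, not infinity.
* Medoid and closest-frame ties break to the lowest index; an exclusion
  window that leaves no candidates is an error.
* Alternate locations in PDB input keep the highest-occupancy conformer,
  ties to altLoc 'A'; insertion codes are unsupported and error out;
  duplicate (chain, resid, atom_name) identities error naming the
  offender; per-model atom-count drift in multi-model files errors naming
  the model.
* Fits run with positivity lower bounds and at most 200
  Levenberg-Marquardt iterations; zero-residual (noiseless) fits are
  handled by the LM implementation without special casing.

## Workflow and problem sizes

The `analysis/` scripts run the whole study at sizes chosen to keep each
stage in seconds while leaving the statistics stable: 40 atoms per domain
(260 atoms per molecule), 40-frame trajectories with 0.15 Angstrom jitter
for the three construct-like motion scripts, 171-point melt grids in
triplicate, and 12-point titrations in triplicate at 3% noise. The
stage-2 alignment is anchored on the Fc alpha-carbons rather than the whole
molecule: the stalk is the stable part, and a whole-molecule fit would let
the moving arms drag the laboratory frame that the z-axis metric is defined
in — the same reasoning that motivates the pivot/center framework in the
first place. Property tests that need asymptotics (the RMSF limit) use
2000-frame jitter trajectories on 25-30 atoms.

## Known limitations

* The stand-in potential supports relative, not absolute, energetics;
  printed energy percent changes from proprietary force-field analyses are
  not reproducible from it and are treated as qualitative anchors only.
* Heavy-atom hydrogen-bond detection over-counts relative to
  angle-filtered detection on hydrogenated structures.
* The medoid representative is a surrogate for whatever clustering a
  proprietary engine performs; on a monotone motion it sits mid-trajectory
  rather than at the extreme.
* Multi-transition melt curves are out of scope — the estimator takes the
  dominant transition only.
* No periodic-box handling: trajectories must be whole-molecule,
  solvent-stripped.
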