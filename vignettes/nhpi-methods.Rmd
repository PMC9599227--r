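---
title: "Methods: geometry, screening and ensemble analysis of NH-pi interactions"
author: "nhpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, screening and ensemble analysis of NH-pi interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhpi)
```

## The geometric model

An NH–π interaction is described here entirely by heavy-atom geometry.
For a donor–ring pair we measure three *bond-conformation* parameters —
the nitrogen–centroid distance `d_nm`, the acute approach angle `theta`
between the centroid→nitrogen vector and the ring normal, and the
hydrogen-side angle `omega` (N–H···M at the hydrogen) — and three
*side-chain-position* parameters: the reference-carbon distance
`d_cg_pi`, its signed elevation `tau` above the ring plane, and the
in-plane azimuth `chi` of the Cγ→N direction relative to the ring's
substituent bond.

**Ring frame.** The centroid M is the arithmetic mean of the six ring
carbons, and the normal is the least-squares plane normal (smallest
right singular vector of the centred coordinates).  A least-squares
plane leaves the normal's sign free, so we fix it with the right-hand
rule on the canonical atom traversal (CG–CD1–CE1–CZ–CE2–CD2 for Phe,
C1…C6 for toluene/benzene): counter-clockwise traversal viewed from the
+normal side.  This makes signed elevations `tau` reproducible — and it
means a chemically equivalent ring flip (the D1/D2, E1/E2 relabelling)
flips the sign of `tau`, which is exactly why ensembles show symmetric
`tau` populations on either side of the plane.  No post-hoc sign
folding is applied.  Rings with a planarity RMS above 0.1 Å are flagged
(`planar_ok = FALSE`) but still usable.

**Hydrogen placement.** Crystallographic models rarely contain
hydrogens, so the two amide hydrogens are always constructed
theoretically and any file hydrogens are ignored: each H is placed
1.0 Å from N (configurable), in the amide plane defined by the carbonyl
carbon, carbonyl oxygen and amide nitrogen, in trigonal sp² geometry
(both H–N–C angles 120°, the two H on opposite sides of the N–C axis).

**Conventions that had to be decided.**

* `omega` is measured *at the hydrogen* (the hydrogen-bond convention:
  donor–H···acceptor) and maximised over the two amide hydrogens — the
  hydrogen oriented toward the ring is the interacting one.  The index
  of the winning hydrogen is recorded per pair (`h_used`).
* `d_cg_pi` defaults to the reference-carbon→centroid distance.  A
  perpendicular distance to the ring plane is also implemented
  (`geometry_config("plane")`), but the centroid convention is the one
  consistent with jointly observed values of `d_nm`, `tau` and
  `d_cg_pi` in real collagen Gln–Phe pairs: with the pair at
  `d_nm` 3.3 Å and `tau` ≈ 61°, a centroid distance of ≈ 5.3 Å implies
  a Cγ···N separation of ≈ 2.4 Å — precisely the geminal distance of a
  rigid amide — whereas the plane-distance reading would imply an
  impossible ≈ 4 Å separation.
* `chi` is reported unsigned in [0°, 180°], matching how observed
  ranges of this angle are quoted in the literature.  When the Cγ→N
  vector is (numerically) parallel to the ring normal its in-plane
  projection vanishes and `chi` is reported as `NA`, not 0.
* `theta` is folded to the acute angle, so it is independent of the
  normal's sign.

## Screening

Candidate pairs are enumerated per (donor residue, ring residue)
combination with `d_nm` up to 4.5 Å (the enumeration ceiling is
deliberately wider than the interaction cutoff so that near-threshold
pairs are visible).  The NH–π classification applies the standard
empirical cutoffs as *strict* inequalities:
`d_nm < 4.3 Å ∧ theta < 25° ∧ omega > 120°`.  A pair exactly on a
boundary fails; this is tested explicitly.  The symmetric form of the
θ cutoff sometimes quoted (−25° < θ < 25°) collapses to θ < 25° because
θ is defined acute.

**Collagen register.** In a Gly–X–Y triple helix, a donor at the Y
position can contact a ring at the X position of the *next* triplet on
the next chain (*axial*) or the X of its own triplet (*lateral*).
Chains are ordered leading → middle → trailing either from
configuration or by inference: C-alpha positions are projected on the
common principal axis, a line `axial_position ~ residue_number` is
fitted per chain, and chains are ranked by intercept (the leading chain
sits furthest along the axis at equal residue number, reflecting the
one-residue stagger).  The Gly phase of each chain is inferred from the
residue numbers of its glycines.  Non-collagen input gets the register
label `n/a` with a warning rather than an error.

**Dataset filters.** Entry-level metadata filters (resolution ≤ 2.0 Å,
R-factor ≤ 0.25, minimum chain length 40, experimental entries with
full coordinates; all bounds inclusive) are applied by
`filter_dataset_entries()`.  Sequence-identity culling is *not*
performed — a pre-culled representative list is an input, since
redundancy removal is a service of dedicated servers and depends on a
sequence database snapshot.

## Solvent accessibility and burial

`shrake_rupley_sasa()` is a from-scratch Shrake–Rupley implementation:
each atom's probe-expanded sphere (probe 1.4 Å) carries a
deterministic Fibonacci-lattice quadrature (960 points by default;
doubling the count moves the analytic single-sphere case by < 0.5%),
and a point is accessible when outside every neighbour's expanded
sphere.  Points falling exactly on a shared boundary are owned by the
lower-index atom so that degenerate overlaps still partition the
surface.  Hydrogens are excluded (heavy-atom convention) and waters are
excluded by default.  Radii follow the Chothia/NACCESS tradition
(C 1.70, N 1.55, O 1.52, S 1.80 Å, …).

Pair accessibility is the sum of the two whole residues' ASA — side
chain plus backbone — computed in the context of the full structure.
Burial classes: buried < 30 Å²; 30–60 Å² labelled *intermediate* (a gap
between the published bounds that we report explicitly rather than
silently merging); partially exposed 60–120 Å² (exclusive); fully
exposed ≥ 120 Å², the threshold chosen by continuity with the published
bins since no explicit number is in circulation.  Because this
implementation is not numerically identical to DSSP's, burial-class
counts from DSSP-based surveys are validation context, not acceptance
values.

## Ensembles and trajectories

Multi-model PDB files serve as the trajectory format (any MD engine can
export one).  Per frame, the full six-parameter geometry of a chosen
pair is extracted; the *cutoff occupancy* is the mean of the per-frame
pass indicator.  Density maps are plain 2-D histograms with default bin
widths of 0.1 Å for distances and 5° for angles (no widths are
standard, so these are package defaults, chosen to resolve the
0.2–0.5 Å / 5–15° spread of thermally fluctuating pairs); occupied-bin
fractions sum to 1, a third parameter is averaged per bin as a colour
channel, and the modal bin is reported with ties broken toward smaller
first-axis values.

Ring superposition for population views uses the orthogonal Procrustes
(Kabsch) solution onto an ideal reference hexagon, with the same rigid
transform applied to the donor atoms; opposite planted elevations land
on opposite sides of the reference plane.

## Melting temperature

A CD thermal-denaturation curve is reduced to a folded fraction
`F(T) = (θ(T) − θ_U(T)) / (θ_F(T) − θ_U(T))`, where `θ_F` and `θ_U` are
linear fits to the folded and unfolded baselines.  The baseline windows
default to the lowest and highest quarters of the temperature range —
no universal windows exist, so they are explicit, overridable
parameters.  Tm is the temperature where `F` crosses 0.5, located by
linear interpolation between the bracketing measurements; a curve that
never crosses is a "no transition" error, and a non-monotone crossing
yields the first crossing with a warning.  The normalisation makes the
estimate agnostic to the sign of the transition.

## The acetamide–toluene scan lattice

The model system for Gln–Phe energetics is acetamide over toluene.  The
frame is anchored on the toluene: origin at C1 (the ring carbon bearing
the methyl), x-axis along methyl→C1, z along the ring normal, y
completing a right-handed frame.  "CM" is interpreted as the methyl
carbon (the ring centroid is already called M).  The lattice spans
x, y ∈ [0, 4.8] Å every 0.4 Å and z ∈ [2.0, 5.0] Å every 0.2 Å, both
endpoints included: 13 × 13 × 16 = 2704 points, which is the quadrant
sufficient by the molecule's two mirror symmetries.

At each site the acetamide is placed rigidly in a canonical
orientation — N at the site, the N–H bisector toward −z (both
hydrogens toward the ring), amide plane containing the z-axis.  Real
scans relax all non-nitrogen atoms at each site; a geometry generator
cannot reproduce a relaxed orientation without an energy model, so the
canonical orientation is a documented limitation, and the per-point
*derived* geometry refers to this rigid placement.  One consequence is
worth stating: because the frame origin is C1 while the centroid M sits
1.39 Å away along +x, the lattice point at x = y = 0 is *not* on the
ring axis and has θ = atan(1.39/z) ≠ 0; θ vanishes only directly above
M.  Per-point complex geometries are written as XYZ files with a
manifest; energies come back keyed by lattice index.  The package locates
the global minimum (ties to the first index), builds the minimum-energy
envelope against `d_nm` for near-axial points (0 < θ < 20°), and
projects energy against `tau` under an angular filter that can be taken
on `chi` or on `tau` — both conventions appear in the literature, so
the output names the one used.

## The synthetic generator

The synthetic module is the package's test bed and defines the
conditions under which the pipeline is validated:

* `plant_pair_fragment()` constructs coordinates realising a requested
  parameter set on an idealized rigid fragment pair (ring C–C 1.39 Å;
  amide N–C 1.33 Å, C–C 1.52 Å, C=O 1.23 Å, sp² angles).  N is placed
  on the cone fixed by `d_nm`/`theta`; `tau`/`chi` place the reference
  carbon by intersecting the elevation ray with the rigid-geometry
  sphere (both root branches are searched); the remaining amide spin is
  solved for `omega` by bracketed root finding with tangential-contact
  handling (so `omega = 180°` is exactly representable).  Requests the
  rigid geometry cannot satisfy are rejected naming the violated
  constraint — e.g. a small maximum-over-hydrogens `omega` is
  unreachable because the second hydrogen, 120° away, always points
  somewhere.  Over-determined six-parameter combinations measured from
  real, non-ideal structures may be infeasible on the ideal fragment
  even when each parameter is individually legal.
* `generate_decoy_structure()` embeds known numbers of passing and
  failing pairs, sampled with margins of at least 0.2 Å / 5° from every
  cutoff so that classification is unambiguous, posed with seeded
  random rigid transforms, 18 Å apart (no cross-pair contacts below the
  enumeration ceiling).
* `generate_trajectory()` plants an exact ⌊fraction·n⌋ subset of
  passing frames with 0.02 Å Gaussian coordinate jitter — roughly the
  coordinate precision of a well-refined structure, and far smaller
  than the sampling margins.
* `generate_melt_curve()` produces a two-state sigmoid
  (`F = 1/(1 + exp((T − Tm)/width))`, width 2 °C — a sharp, cooperative
  transition typical of short triple-helical peptides) on linear
  baselines over 4–80 °C, with seeded Gaussian noise.  An amplitude of
  0 yields a baseline-only curve.

What the generators deliberately do *not* emulate: real side-chain
flexibility and internal-coordinate variation (bonds and angles are
ideal), crystallographic disorder beyond the altloc policy, correlated
frame-to-frame dynamics (trajectory frames are independent), and
realistic triple-helix packing (decoys are isolated fragments).
Passing tests therefore demonstrate correctness of the measurement,
screening and recovery machinery — not field performance on any
particular structure corpus.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use: 2704-point scan
lattices; 1000 planted specs for round-trip verification (observed
worst-case error ~1e-12 against a 1e-6 requirement); 10,000 random
placements against an independently coded brute-force oracle (1e-9
agreement); decoy structures up to 20 + 20 pairs; 2000-frame
trajectories for occupancy recovery; 100 noisy curves for Tm recovery.
Root finding uses 721-point bracketing grids with `uniroot` at 1e-14
tolerance.  Angles are computed with `atan2` of cross/dot products
(stable near 0° and 180°); the oracle deliberately uses `acos` and
Newell's polygon normal instead, so agreement is not an artefact of
shared formulas.

## Known limitations

* Only six-membered carbocycles (Phe, toluene, benzene) are rings in
  v1; His/Trp five-membered rings and backbone N–H donors are out of
  scope.
* No symmetry expansion: pairs across crystallographic symmetry copies
  are not seen.
* Registered collagen inference assumes shared residue numbering across
  the three chains and at least two glycines per chain.
* The scan module emits geometries and ingests energies; it never
  evaluates an energy itself.
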