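# nhpi

Geometric detection and analysis of side-chain **NH–π interactions**
between amide donors (Gln, Asn, acetamide) and phenyl rings (Phe,
toluene) in protein structures, with particular support for collagen
triple helices.

An NH–π contact is an attractive interaction, intermediate between a
hydrogen bond and pure dispersion, in which a polar N–H group points at
the face of an aromatic ring.  `nhpi` describes each donor–ring pair by
six parameters measured from heavy-atom coordinates:

* **d_NM** — distance from the amide nitrogen N to the ring centroid M;
* **θ** — acute angle between the M→N vector and the ring normal
  (small θ: the donor sits over the ring face);
* **ω** — the N–H···M angle at the hydrogen, maximised over the two
  amide hydrogens (large ω: the H points at the ring centre);
* **d_Cγ–π** — distance from the donor reference carbon (Gln Cγ, or the
  acetamide methyl carbon) to the ring centroid;
* **τ** — signed elevation of the reference carbon above the ring plane
  (−90°…90°, positive on the +normal side);
* **χ** — unsigned in-plane azimuth (0°…180°) of the Cγ→N direction
  relative to the ring substituent (Cβ→Cγ) bond.

Amide hydrogens are always placed theoretically (N–H = 1.0 Å, trigonal
sp², in the amide plane); hydrogens present in the input are ignored.
A pair is classified as an NH–π interaction when

```
d_NM < 4.3 Å   and   θ < 25°   and   ω > 120°        (strict inequalities)
```

Around that core the package provides:

* a minimal fixed-column **PDB reader/writer** (single- and multi-model,
  altloc policies, REMARK 2/3 metadata);
* **pair enumeration and screening** over a structure, with collagen
  axial/lateral register classification and dataset metadata filters
  (resolution ≤ 2.0 Å, R ≤ 0.25, chain length ≥ 40);
* a **Shrake–Rupley** solvent-accessible-surface implementation
  (deterministic Fibonacci quadrature) with pair burial classes
  (buried < 30 Å², intermediate 30–60 Å², partially exposed 60–120 Å²,
  fully exposed ≥ 120 Å²);
* **ensemble analysis**: least-squares ring superposition, 2-D density
  maps over geometric parameters, per-pair cutoff occupancy along
  multi-model trajectories;
* **melting-temperature extraction** from CD thermal-denaturation
  curves via linear baseline fits and the folded fraction
  `F(T) = (θ(T) − θ_U(T)) / (θ_F(T) − θ_U(T))`, with Tm at F = 0.5;
* the **acetamide–toluene scan lattice** (x, y: 0–4.8 Å every 0.4 Å;
  z: 2.0–5.0 Å every 0.2 Å; 13 × 13 × 16 = 2704 points) in the
  toluene-anchored frame, emitted as XYZ files for any external
  quantum-chemistry engine, and ingestion of the resulting energies
  into minima and projection tables — energies are never computed here;
* a **synthetic-data module** that plants donor–ring fragments at
  prescribed geometry (the constructive inverse of the measurement),
  builds decoy structures with known pass/fail composition, trajectories
  with a planted cutoff occupancy, and two-state melting curves — so the
  entire pipeline is testable without downloads.

## Worked example

```r
library(nhpi)

# a synthetic structure with 2 planted NH-pi pairs and 2 decoys
s <- generate_decoy_structure(2, 2, seed = 4)
recs <- screen_pairs(enumerate_candidate_pairs(s))
recs[, c("donor_resno", "ring_resno", "d_nm", "theta", "omega", "pass")]
#>   donor_resno ring_resno  d_nm  theta omega  pass
#> 1           1          2 3.544  2.152 139.5  TRUE
#> 2           3          4 3.205 15.831 138.0  TRUE
#> 3           7          8 2.980 51.622 139.2 FALSE
attr(recs, "pass_fraction")
#> [1] 0.6666667

# melting temperature from a noisy two-state CD curve planted at 40 C
mc <- generate_melt_curve(tm = 40, noise_sd = 30, seed = 1)
melting_temperature(mc$temperature, mc$ellipticity)$tm
#> [1] 39.89

# the quadrant scan lattice for external QM engines
nrow(generate_scan_grid()$points)
#> [1] 2704
```

Three pairs appear because one decoy fails by distance (7–9 Å from any
ring centroid) and is never enumerated; the remaining decoy is
enumerated but fails the θ cutoff.  The planted pairs pass all three
cutoffs, and the recovered Tm is within 0.11 °C of the planted value at
1% noise.

A thin command-line wrapper ships in `inst/exec/nhpi`
(`nhpi scan`, `filter`, `sasa`, `traj`, `melt`, `grid`, `synth`).

## Documentation

The methods vignette (`vignettes/nhpi-methods.Rmd`) describes the
geometric model, all conventions and defaults, the design of the
synthetic generators, and known limitations.
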