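---
title: "Mining anion-aromatic contacts: model, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining anion-aromatic contacts: model, geometry and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anionarene)
```

## The problem and the coordinate model

Anions close to aromatic rings occur in two very different flavours: over the
positively polarised face of an electron-poor ring (the anion-pi contact
proper) and edgewise, near the ring plane, where C-H...anion contacts and
charge-assisted hydrogen bonds dominate. To survey both without bias, every
anion found inside a sphere of radius 5 Å around a ring centroid is
described in the ring's own cylindrical frame:

* `x` — distance from the centroid to the anion's projection onto the
  least-squares ring plane,
* `h` — absolute height above that plane (the two faces are aggregated;
  the raw sign is kept separately as `side`),
* so that `r^2 = x^2 + h^2` is the centroid distance.

The reason for preferring `(x, h)` over the conventional polar `(R, alpha)`
system is volumetric: equal-size `(x, h)` bins are thin cylindrical shells
of volume `2 * pi * (x2^2 - x1^2) * dh` (the factor 2 folds both faces of
the plane), which grows only linearly in `x`, whereas equal-angle polar
slices grow like `R^2` and therefore accumulate counts far from the ring
even when the underlying density is flat. `build_histograms()` always
reports both raw counts and counts divided by the exact bin volume; the
package's test suite demonstrates the artefact directly by histogramming
uniform points in the ball (flat density, yet radially increasing counts).

## Regions A, B and C

Three rectangles in the folded `(x, |h|)` half-plane mark the accumulation
areas seen in density maps: **A** over the ring skeleton (the anion-pi
area), **B** over the ring-substituent bonds, and **C** near the ring plane
at the sphere's edge. Each rectangle denotes a solid of revolution mirrored
across the plane and clipped to the 5 Å ball.

The exact rectangle coordinates are not universal constants; what is fixed
is their volume budget — 13.1%, 13.8% and 20.2% of the ball for A, B and C.
The shipped `default_region_spec()` therefore fixes figure-plausible
h-windows (A and B span `|h|` in [1.6, 3.9) Å, C spans [0, 1.6) Å) and
solves the x-boundaries analytically so the clipped-solid volumes meet that
budget exactly:

```{r}
spec <- default_region_spec()
unlist(spec$A); unlist(spec$B); unlist(spec$C)
region_volume(spec)
```

Two numerical conventions matter. Region membership is half-open,
`[min, max)` in both coordinates, so boundary points are assigned
deterministically. And region C is clipped by the sphere: the volume
formula integrates `min(h_max, sqrt(R^2 - x^2))`, the spherical-cap
correction that `region_volume(method = "monte_carlo")` verifies by
sampling.

## What counts as a ring, an anion, a cation, a donor

*Rings.* Phe, Tyr, His, Trp (two rings) and the nucleobases (purines
contribute a 6- and a 5-membered ring, counted separately) are matched by
atom-name templates. Ligand rings are perceived generically: a covalent
graph (bond when the interatomic distance is under the covalent-radius sum
plus 0.45 Å — deliberately tolerant at 2.5 Å resolution), 5/6-cycles of
C/N/O/S whose members deviate from the least-squares plane by at most
0.10 Å and have at most three heavy-atom neighbours. The planarity
tolerance cleanly separates aromatic rings from chair cyclohexanes
(maximum deviation about 0.25 Å).

*Anions.* Asp/Glu side-chain and C-terminal carboxylates, the charged
phosphate oxygens of nucleotides (`OP1`/`OP2` and aliases; ester oxygens
excluded), and a user-editable dictionary of ligand anions (sulfate,
phosphate, acetate, formate, nitrate, citrate, malonate, halides). A site
is one charged group, not one oxygen: each ring-site pair yields a single
record whose representative atom is the site atom nearest the centroid,
which avoids double-counting carboxylates. Trigonal groups carry a fitted
plane so that the anion-plane/ring-plane angle can be histogrammed; sites
with any atom within 3.0 Å of a metal are flagged `metal_bound` and
excluded from orientation statistics (ion pairs follow the metal, not the
ring).

*Cations.* Metal atoms (each iron of an Fe-S cluster is an independent
site), Arg guanidinium (positioned at `CZ`, which coincides with the
nitrogen centroid on ideal geometry) and Lys ammonium (`NZ`). His is
treated as a ring and a potential donor, never as a cation.

*Donors.* Any N/O/S heavy atom with a covalently attached hydrogen. When a
model carries no hydrogens, `add_amino_acid_hydrogens()` places the
standard polar hydrogens of amino acids at ideal geometry (N-H 1.01 Å,
O-H 0.96 Å, S-H 1.34 Å; sp2 in-plane, sp3 staggered); deposited
protonation states are trusted and left untouched, and ligands never
receive hydrogens, so ligand donors count only when the file provides
their hydrogens.

## Ternary synthons

Seven co-existing motifs are tested for every pair, with the thresholds in
`default_synthon_thresholds()` (distances in Å, angles in degrees):

| motif | meaning | criteria |
|---|---|---|
| i | ring...anion...cation | metal-anion < 3.25, same side (waived in C), ring not metal-bonded |
| ii | anion...ring-cation | metal within 3.0 of a ring atom and < 3.25 from the anion |
| iii | anion...ring...cation | cation < 5 from the centroid, inside the 45° sector, opposite side (waived in C), anion-cation > 3.25 |
| iv | anion...ring- - -cation | metal within 3.0 of any quadrupole-residue atom, anion-cation > 3.5 |
| v | ring...anion...H-donor | D-H...A angle > 130, acceptor-donor < 3.2, acceptor-H < 2.2 |
| vi | anion...ring...ring (parallel) | inter-plane angle < 15, centroid distance < 5, offset h > 1.6 and x < 2.2, 15° sector |
| vii | anion...ring...ring (perpendicular) | centroid distance < 5 and three > 70° angle conditions |

The sets overlap by design; a pair matching none is "rest". The 3.0 Å
metal-coordination cutoff operationalises "coordinated directly" as a
typical coordination bond length and is configurable; the gap between the
3.25 Å (close) and 3.5 Å (far) anion-cation thresholds means a cation at
3.3-3.5 Å can satisfy motif iii but not iv, exactly as the two printed
criteria imply. In motif v the acceptor may be any site atom of the anion
(the representative-only interpretation is stricter; the difference is a
documented choice). Hydrogen-bond partners are all recorded, since one
anion frequently binds several donors.

## The synthetic-structure generator

`make_fixture()` and its helpers build minimal structures with exactly
known geometry: idealised ring templates (regular polygons with 1.39 Å
sides, fused pentagons for indole and purines), anion groups whose anchor
atom is planted at a prescribed `(x, h, azimuth, side)` with the rest of
the group pointing away from the centroid (so the anchor is provably the
representative atom), cations and donor probes at prescribed positions,
and secondary rings at prescribed plane angles. `make_helix_fixture()`
plants a Phe ring and a Glu carboxylate on an ideal helix backbone
(100°/1.5 Å per residue) so the mined pair has the classic one-turn
separation `delta = rID - aID = -4`; `make_gnra_fixture()` plants a
phosphate over a guanine in a G-N-R-A sequence at `delta = -2`. A fixed
seed controls every random azimuth, placements that bring two entities
within 1 Å are rejected, and the mmCIF writer emits six-decimal
coordinates so file round-trips preserve planted geometry to 1e-6 Å.

What the fixtures deliberately do **not** emulate: thermal noise and
coordinate error, realistic side-chain rotamers and backbone covalent
geometry away from the planted contact, crystal packing, occupancy
disorder, or chemically complete residues. Passing tests therefore certify
the geometry, bookkeeping and classification logic of the pipeline — not
the biological frequencies of the motifs, which require real structure
ensembles.

## Policies and degenerate inputs

* Structures without a resolution record (e.g. solution NMR) fail the
  default resolution filter; `keep_unresolved = TRUE` overrides.
* Only the first model of multi-model files is used.
* For alternate locations, the highest-occupancy altloc wins; exact ties
  go to the lexicographically smallest code, for determinism.
* Sequence separations use author numbering; insertion codes make the
  separation undefined (`NA`) rather than silently wrong.
* Deduplication keys on (ring-chain cluster, anion-chain cluster, ring
  code, anion code and site atom, separation or inter-chain marker,
  region); the first occurrence in `(pdb_id, ring)` order is kept, making
  the reduction idempotent and order-independent. Without a cluster map
  every chain is its own cluster and a warning says so.
* Ring normals have arbitrary orientation; all side-dependent logic is
  relative (same side / opposite side), never absolute.
* Bins with `x` below one bin width have near-zero volume; their densities
  are reported but flagged `low_volume` so plots can cap them.
* DSSP output is consumed from files (classic format); the assignment
  algorithm itself is external, and the pipeline degrades gracefully when
  no DSSP annex is available. The same applies to sequence-cluster maps.

## Problem sizes in the shipped tests

The test suite verifies the classifier against an independent brute-force
geometric oracle on 1000 randomised configurations and the sphere search
against an exhaustive double loop on 160 random structures; region-volume
Monte-Carlo uses 1e7 points in the acceptance check and 1e6 elsewhere;
histogram uniformity uses 2e5 points. These sizes give comfortable
statistical resolution for every property tested while keeping the whole
suite around a minute on one CPU.

## Known limitations

* Formal-charge perception for arbitrary ligands is out of scope: the
  anion dictionary covers the common codes and is user-extensible.
* No symmetry expansion: contacts across crystallographic symmetry mates
  are not generated; only deposited coordinates are searched.
* Motif vii (T-shaped stacking) peaks near 5 Å centroid separation, at the
  very edge of the search sphere; a complete stacking survey needs a
  larger radius than the anion-centric 5 Å used here.
* Hydrogen placement covers the standard amino-acid donors only; unusual
  protonation states are taken from the file or missed.
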