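---
title: "Target-templated design of heterochiral macrocyclic peptides: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-templated design of heterochiral macrocyclic peptides: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrocycler)
```

## The problem

Head-to-tail cyclized peptides that mix L- and D-amino acids occupy a
useful middle ground between small molecules and biologics: large enough
to engage flat protein–protein interfaces, rigid enough to bind with
modest entropic cost, and resistant to proteolysis. Designing one
against a chosen protein surface requires solving two coupled problems
at once: finding closed-ring backbone conformations that present a
productive face to the target, and choosing side chains — of either
chirality — that complement the target surface while stabilizing the
ring's own fold.

`macrocycler` implements a complete desk-scale version of this protocol:
a fixed *hotspot* residue docked on the target seeds the design;
poly-glycine arms are extended from it and closed into rings of 7–12
residues by an analytic kinematic-closure solver; closed backbones are
screened by energy and hydrogen-bond filters; surviving backbones are
sequence-designed under the phi-sign chirality rule; designs are ranked
by interface metrics; and each candidate's structural pre-organization
is assessed from its conformational energy landscape.

## Backbone model

All peptide geometry is internal-coordinate based: bonds and angles are
fixed at Engh–Huber-style reference values (N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°)
and conformations are parameterized entirely by torsions. Chains are
realized by sequential NeRF-style frame extension. Amides are planar
trans (omega = 180°) by default; cis sampling is off. The only hydrogen
built is the backbone amide H (in-plane, 1.01 Å); side chains are heavy
atom only. D-residue topologies are exact mirrors of their L partners —
the CB-placing improper and every fixed side-chain torsion are
sign-negated — so a D-chain built with negated torsions superposes onto
the mirrored L-chain to machine precision (a property the test suite
asserts).

The CA stereocentre convention is dihedral(C, N, CA, CB) = −122.5° for
L residues, verified during development against independently generated
small-molecule conformers; Thr and Ile branch offsets follow their
natural (2S,3R) and (2S,3S) diastereochemistry.

## Ramachandran bins and the chirality rule

Torsion sampling is biased by coarse ABEGO-style bins. The upper-case
family A (phi ∈ [−180, 0), psi ∈ [−75, 50)), B (phi < 0, remaining psi),
G (phi ≥ 0, psi ∈ [−100, 100)) and E (phi ≥ 0, remaining psi) tiles the
torus; the lower-case family a/b/g/e is its exact sign mirror. Within a
family bins are disjoint and covering; the two families overlap each
other by construction, which is how both chiral halves of the plot are
sampled. Default weights are 1 for the preferred regions (A, B, a, b)
and 0.5 for G/E/g/e; both the boundaries and weights are plain data
(`default_rama_bins()`) and configurable. Pro and D-Pro narrow phi to
[−75, −55] and [55, 75] respectively when the identity is known.

Chirality assignment is the phi-sign rule: positions with backbone
phi < 0 are designed as L-amino acids, positions with phi > 0 as
D-amino acids; Gly is achiral and allowed anywhere. The measure-zero
boundary phi = 0 is assigned L by convention.

## Triaxial kinematic closure

Ring closure is solved analytically rather than by iterative
minimization. With ideal geometry and fixed non-pivot torsions, the
backbone between consecutive pivot C-alphas is a rigid body — the pivot
torsions rotate about bonds passing through the pivot CA itself, so
they do not deform the segments. The three CA···CA virtual distances
are therefore fixed and the pivot C-alphas form a rigid triangle. Each
segment keeps one degree of freedom, a spin sigma about its triangle
edge, and closure reduces to restoring the ideal N–CA–C angle at the
three pivots: three equations, each bilinear in the sines/cosines of
two adjacent spins. Given sigma_1, each equation has at most two
branches for the next spin; the remaining scalar residual is
root-solved in sigma_1 over a 1440-point grid with bisection refinement
(tolerance ~1e-12 radians). The solution count is bounded by 16, the
classical degree bound of the closure polynomial. Infeasible torsion
draws (triangle inequality violated, or no real branch) return an empty
set, not an error.

Two independent checks back the solver: every returned solution is
rebuilt by forward kinematics and must close (C–N bond within 0.01 Å,
pivot angles within 1e-3°), and on small rings the full solution set is
compared against a purely numerical scan oracle that rotates explicit
segment coordinates and never touches the solver's branch algebra —
counts agree and torsions match to better than 1e-3°.

Anchored sampling solves the ring in a floating frame and then grafts
it rigidly onto the anchor by superposing the anchor residue's N/CA/C
triad, after which the anchor coordinates are set bit-identically. For
ideal-geometry fixtures the graft is exact; for anchors extracted from
crystal structures the residue's own deviation from ideal geometry
(typically a few hundredths of an Å) is absorbed at the two ring bonds
flanking the anchor — a documented approximation of desk scale.

## Energy model

The score is a small decomposable potential, not a re-implementation of
any production force field; its purpose is to make the filter cascade,
design moves and funnel analysis well-defined and testable:

* **steric** — 6–12 Lennard-Jones on heavy-atom pairs with Bondi-style
  radii (C 1.70, N 1.55, O 1.52, S 1.80 Å), well depth 0.05 per pair at
  contact, continued linearly below 0.6× contact so clashes score large
  but finite. Same-residue pairs, adjacent backbone–backbone pairs and
  the two 1–4 pairs through the CB are excluded.
* **hbond** — −0.5 per bond scaled by a distance/angle falloff.
  Backbone–backbone bonds use the explicit amide H (H···A ≤ 2.5 Å,
  D–H···A ≥ 120°, ring neighbours excluded); classes without built
  hydrogens (side chains, the target) use a heavy-atom donor–acceptor
  criterion (D···A ≤ 3.2 Å, base angle ≥ 90°).
* **rama** — −log of the normalized weight of the occupied bin, 0 in
  preferred regions, ~0.35 per residue in the half-weight regions.
* **composition** — applied only while designing: +1 per Gly, +1 per
  Ala, −0.5 per Pro/D-Pro, to push designs toward chemical diversity
  and turn-stabilizing prolines.

There is no solvation and no electrostatics; this is a stated
limitation, and the E ≤ 0 filter threshold is configurable because the
scale of this potential is its own. Every term is rigid-motion
invariant and mirror invariant (the potential is achiral), which the
suite asserts.

## Filters, design and ranking

Sampled backbones are first clash-screened against the target
(hard-sphere, 0.6× summed radii), then scored; solutions with total
E > 0 are discarded, as are solutions with fewer than 2 intramolecular
backbone hydrogen bonds (both thresholds configurable). Sequence design
is Metropolis Monte-Carlo over (identity, rotamer) moves at every
non-anchor position — identities restricted by the phi-sign rule, Cys
and Met excluded by default as synthesis liabilities — under a
geometric temperature ladder (3.0 → 0.3 in 10 stages, 5000 moves by
default), followed by a local chi refinement (±10° in 2.5° steps) of
the best state. The rotamer library is the compact canonical set chi ∈
{−60, 60, 180} per rotatable bond, with D rotamers as sign mirrors; the
hotspot-scan variant adds ±20° sub-samples around chi1/chi2. Move
proposals see the same steric and composition terms as the final score
plus a distance-weighted polar-contact proxy for the side-chain
hydrogen-bond classes; the angle criterion is applied only at final
scoring, which is always the full potential.

Ranked output orders designs by interaction energy (E(complex) −
E(peptide) − E(target), which for this potential is exactly the cross
steric plus cross hydrogen-bond terms), with buried interface area,
shape complementarity and total hydrogen-bond count as tie-breaks.

## Interface metrics

Solvent-accessible surface area is Shrake–Rupley with a deterministic
golden-spiral dot set (960 dots/atom, probe 1.4 Å); buried interface
area is the two-sided total SASA(a) + SASA(b) − SASA(a ∪ b). Shape
complementarity follows Lawrence–Colman: van der Waals surface dots of
each body (self-burial only), interface dots within 1.5 Å of the
opposing surface, S = (n̂_a · −n̂_b) exp(−0.5 d²) against the nearest
opposing dot, and the statistic is the mean of the two per-surface
medians. Because the surfaces are dot-sampled sphere patches rather
than a smoothed molecular surface, ideal flat contacts score ~0.92
rather than 1.0, and rigid-motion invariance of the dot-based areas
holds to a few percent at default density (both behaviours are pinned
by tests).

## Energy landscapes and the funnel verdict

`predict_landscape()` re-samples closed conformers of a designed
sequence without the target: per-position Ramachandran bins matching
each position's designed chirality, random pivots, closure, greedy
side-chain repacking with identities fixed, and scoring of the peptide
alone. The design conformation itself is injected as sample 0. The
verdict is the paper-style criterion: the design is pre-organized when
the lowest-energy sample lies within 1.0 Å backbone RMSD of the
designed conformation. A Boltzmann-weighted pre-organization score is
deliberately not computed; only the RMSD-of-minimum criterion is used.

## Synthetic fixtures: what they do and do not show

All tests run without network access on generated structures:

* `make_toy_target()` builds a rigid two-strand antiparallel beta-sheet
  slab (alternating Val/Ala, ~20 residues) with a shallow groove and a
  designated hotspot site + outward normal, emulating a flat, rigid
  protein interface. It is a geometric stand-in: it has no evolved
  sequence, no backbone flexibility and no solvent, so passing tests
  demonstrate correctness of the machinery, not binding predictions for
  any real target.
* `make_ideal_macrocycle()` returns exactly closed rings from frozen
  torsion templates. The `"turns"` hexapeptide template (phi = 64, 177,
  −89, 75, 89, −130; psi = −35, −11, 42, 73, 1, 84) was found by
  closure sampling during fixture construction and frozen because it
  closes exactly, carries three transannular backbone hydrogen bonds,
  and — once its positions are assigned L/D identities by the phi-sign
  rule — sits at the bottom of its own chirality-restricted landscape,
  which is what a funnel test substrate needs.

## Problem sizes and determinism

Default desk-scale sizes, chosen as realistic for a single-CPU
workstation session: 10 000 closure attempts per ring size for
production runs (the verification suite uses 2000 across ring sizes
8–10), 2000 landscape samples, 5000 design moves. Every stochastic
stage is seeded explicitly; sampling attempts are independently seeded
(seed + attempt index) so any execution order reproduces the same
result set bit for bit, which the suite checks by re-running the full
pipeline and comparing scorefiles and PDB outputs byte-wise.

## Known limitations

* The potential has no solvation or electrostatics; its E = 0 filter
  threshold is not comparable to any production force field's scale.
* Side chains carry no explicit hydrogens; side-chain hydrogen bonds
  use heavy-atom geometry only.
* The anchor graft absorbs non-ideal anchor geometry at the flanking
  ring bonds rather than closing with the anchor's own bond values.
* Backbones are never minimized in Cartesian space; bond lengths and
  angles stay ideal throughout.
* Proline rings are built at a fixed pucker; the implied CD–N bond is
  not re-closed.
* The `"visual inspection"` step of real design campaigns is out of
  scope: the pipeline reports ranked lists only.
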