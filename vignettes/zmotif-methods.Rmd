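---
title: "Annotating lone-pair…π contacts and Z-step/Z-turn signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating lone-pair…π contacts and Z-step/Z-turn signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zmotif)
```

## The problem

Z-steps are NpN dinucleotides isostructural to the CpG steps of left-handed
Z-DNA: the 5′-nucleobase is *anti* with a C2′-endo sugar, the 3′-nucleotide
is *syn*, the riboses face each other head-to-head, and — the feature this
package is built around — the O4′ oxygen of the 5′-ribose stacks on a face
of the 3′-nucleobase at a vertical distance below 3.5 Å. Such oxygen…π
(lone-pair…π) contacts also close the ubiquitous r(UNCG) tetraloops, whose
CpG step is a Z-step; loops carrying one are called Z-turns. `zmotif`
annotates these contacts in mmCIF/PDB structures, classifies the supporting
conformational features (glycosidic class, sugar pucker, a reduced set of
Leontis–Westhof pair families, stacking faces), and runs symbolic
constraint searches for Z-steps, Z\_anti-steps and the
r(UNNG)/r(GNNA)/r(CNNG) Z-turn and Z\_anti-turn loop signatures.

## The contact model

For an ordered (base, oxygen-owner) nucleotide pair, each backbone oxygen
(OP1, OP2, O2′, O3′, O4′, O5′; base oxygens and nitrogens are never donors)
is expressed in the base's reference frame:

* **center** — unweighted mean of the base heavy atoms (ring plus
  exocyclic substituents; a `centerAtoms = "ring"` toggle exists because
  the exact atom set behind the published convention is not stated);
* **plane** — total-least-squares plane through the same atoms;
* **signed normal** — the positive side is the 3′-face, the face the
  normal points toward in a regular RNA helix. The sign is fixed by a
  stored intra-base convention: positive dot product with
  (N9→C4) × (N9→C8) for purines and (N1→C2) × (N1→C6) for pyrimidines.
  Both conventions give +z in the standard base reference frame, whose z
  axis points 5′→3′ along the reference strand, and the package's A-form
  helix fixture corroborates the sign: with the normal along the strand
  ascent, the O3′ atom — the 3′ linkage — sits on the positive-normal side
  of every base.

A **true contact** requires 2.0 Å < |z| ≤ 3.5 Å with the in-plane
projection strictly inside a ring polygon (the polygon of the 5 or 6 ring
atoms; purines expose two rings). The 2.0 Å lower bound excludes rare
in-plane arrangements and, by the package's reading, applies to all cases
(a toggle `nearLowerBound` exists because the original text states it only
with the contact definition, not with the search procedure). Two **near**
cases soften the boundary: 3.5 Å < |z| ≤ 3.6 Å while inside a ring, or
|z| ≤ 3.5 Å while outside every ring polygon but inside an **expanded
ellipse** — the least-squares ellipse through the ring atoms, scaled about
its center so its boundary passes 0.3 Å radially beyond the most outlying
ring atom. When several oxygens of one nucleotide qualify, the smallest
|z| wins among in-ring candidates and the projection closest to the base
center among lateral near candidates, so each ordered pair carries at most
one annotation. Contacts are rendered both ways round — `sO4′3` (the named
nucleotide's O4′ on the partner's 3′-face) and `s3O4′` — and a bare `n`
prefix marks near contacts, with `n+` matching both in queries. Exact
boundary values (|z| = 3.5 Å) belong to the true band. A nucleotide's own
oxygens over its own base are excluded by default. Candidate pruning uses a
7 Å base-center-to-oxygen radius, which cannot lose contacts because
|z| ≤ 3.6 Å and the expanded ellipses bound the in-plane extent below 3 Å.

## Conformation, pairs and stacking

χ is the O4′–C1′–N9–C4 (purine) / O4′–C1′–N1–C2 (pyrimidine) torsion, with
*syn* = [0°, 90°], *anti* = [150°, 180°] ∪ (−180°, −90°] and everything
else *intermediate*. The published description of *anti* near 120° conflicts
with the conventional range; the windows here follow convention and are
arguments, because Z-step 3′-nucleotides often sit in borderline regions —
the recommended alternative is the s53 stacking constraint. Sugar pucker
uses the standard pseudorotation arctangent over the five endocyclic
torsions, with C3′-endo = [0°, 36°), C4′-exo = [36°, 72°), C2′-endo =
[144°, 180°); a flat ring (amplitude below 1°) is flagged degenerate. The
ribose head-to-head call (opposed O4′→C1′ directions with mutually facing
rings) has no numeric definition in the literature; it is advisory output
only and never a query filter.

The pair classifier is deliberately reduced: it guarantees the families the
canned queries need (cWW and tSW/tWS, plus their near forms) and marks
everything else provisional. Hydrogen bonds are geometric
(donor–acceptor ≤ 3.5 Å, near ≤ 4.0 Å, donor-antecedent angle ≥ 110°), edges
come from a distance-weighted vote over the standard Leontis–Westhof edge
atoms (the 2′-OH counts as sugar edge, which the revised U•G pattern
needs), cis/trans from the sides the two glycosidic bonds take relative to
the C1′–C1′ axis, and true pairs additionally need inter-plane angle ≤ 35°
(near up to 55°) and a lateral, non-stacked arrangement
(|cos| ≤ 0.5 between the inter-center line and each normal — without this
guard, stacked helix neighbours occasionally classify as pairs). Stacking
requires each base center to project within the partner's expanded-ellipse
system at 2.0 Å < |z| ≤ 4.5 Å; the face code reads nt1-face then nt2-face
(s53 = nt1's 5′-face against nt2's 3′-face, the Z-step arrangement), and
"near" stacks pass in exactly one direction. The 4.5 Å bound and the
center-based criterion are this package's plumbing, config-exposed.

## Symbolic queries

A `MotifQuery` holds per-node base masks, covalent "next" edges (same
chain, author-numbering successor, O3′–P ≤ 2.0 Å — the covalent check
guards against chain breaks with consecutive numbering), per-node χ and
pucker constraints, and per-edge pair / stacking / contact constraints in
the text grammar (`tSW UG`, `n+tSW UG`, `sO4′3`, `s53`). Enumeration
anchors on consecutive runs, then filters; hits are deduplicated as ordered
nucleotide tuples and reported in positional order. The canned searches:

* **Z-step** (strict): next + nt1 *anti* + nt1 C2′-endo + nt2 *syn* +
  nt1→nt2 `sO4′3`; `stack_fallback` swaps the *syn* constraint for `s53`.
* **Z\_anti-step**: next + nt1→nt2 `sO4′5` + nt2 *anti* (or `s55`).
* **Z-turns** (six nodes, n-X-N-N-Y-n): loose = sequence mask + the tSW
  closing pair on nodes 2–5 (U•G, G•A or C•G per template); strict adds the
  nt4→nt5 `sO4′3` contact and *anti* on nt3/nt4. No stem closing-pair
  constraint is imposed on nodes 1/6 — the G•A loops in particular are
  mostly pentaloops with a bulged residue. The `zanti_CNNG` template is the
  Z\_anti-turn: cWW C2=G5, nt4→nt5 `sO4′5`, G5 *anti*.

Hit-set similarity uses node-matched RMSD over base heavy atoms + C1′ after
optimal superposition. It is labelled RMSD everywhere: the geometric
discrepancy score of the original search service is not publicly specified,
and an RMSD is the honest substitute.

## Synthetic fixtures: what they emulate

Every annotation rule is testable offline because the fixture module builds
nucleotides from an embedded ideal-geometry table (one conformer per base,
from the standard chemical component definitions) with exact, invertible
control of χ and pseudorotation: the sugar ring is generated from
out-of-plane displacements solved by Newton iteration so the *measured*
phase and amplitude equal the request to 10⁻⁹, and χ is set by rotation
about the glycosidic bond. Multi-nucleotide fixtures place rigid
nucleotides by deterministic derivative-free optimisation against the
defining constraints (O4′ exactly at its target over the 3′-base, hydrogen
bond distances near 2.85 Å, O3′–P continuity, head-to-head riboses,
clash avoidance), then snap each phosphate onto the preceding O3′ at
1.55 Å. Fixtures are geometric, not stereochemically refined: bond
geometry distal to the tested definitions (for example the phosphate arm
after snapping) can be strained, backbone torsion sequences are not
Z-form-realistic, and no solvent exists — so passing tests certify the
annotation logic, not the energetic plausibility of real structures, and
real-structure surveys (contact totals in a ribosome, representative-set
hit counts) still require the corresponding PDB entries.

Two Z-step arrangements are provided. The default places the O4′ over the
six-ring centroid (z = 3.0 Å) with head-to-head riboses. Under the
center-over-ellipse stacking criterion this arrangement cannot also be a
mutual s53 stack — the O4′-to-base-center distance of an *anti* nucleotide
(≈3.9 Å) is longer than any chord available between the centroid position
and the partner's ellipse system — so a `stacked = TRUE` variant slides the
O4′ toward the outer edge of the six-ring (z = 3.4 Å) and drapes the
5′-base over the five-ring flank, satisfying the s53 criterion in both
directions while keeping the true sO4′3 contact. The stacked variant is
what exercises the `stack_fallback` search mode.

Noise is isotropic Gaussian per atom coordinate, seeded and reproducible.
The survey corpora in the tests and the acceptance script use σ = 0.08 Å,
a typical coordinate precision for well-resolved crystallographic RNA;
that level leaves planted signatures intact, which is the point — the
corpus tests recovery, not robustness limits.

## Numerical choices and edge cases

* Ellipse fitting is the direct least-squares conic fit constrained to an
  ellipse; 5 points determine the conic exactly, collinear input errors.
* "Inside a ring" means strictly inside the ring-atom polygon; boundary
  points are outside. A projection inside both purine ring polygons
  (possible only on the fused bond) goes to the ring with the nearer
  centroid.
* The plane fit is total least squares (smallest singular vector); the
  base center is exact, so projections reconstruct points to 10⁻⁹ Å.
* Multi-model files annotate model 1 by default (`model = "all"` is
  available); the published surveys are single-model X-ray/cryo-EM.
* Alternate conformations: the parser keeps the lexicographically first
  altloc; the survey policy `exclude_partial` then drops any nucleotide
  whose ring atoms or backbone oxygens carry occupancy < 1.
* Modified nucleotides are skipped with a logged count; DNA residues are
  skipped unless `dnaAsRNA` maps them onto ribo counterparts for contact
  annotation (DT as U, ignoring the methyl).
* Resolution-filtered surveys exclude structures without a stated
  resolution, with a message.

## Problem sizes

The property suite compares the annotator with a brute-force oracle on
10,000 randomized oxygen placements around each base, checks membership
classification on 10,000 in-plane points, and round-trips 100 random
(χ, P) pairs; the acceptance script rebuilds the fixture corpus (a
three-step Z-helix, a six-pair A-form duplex, four noisy copies of the
UNCG Z-turn and two negative controls) and reports the counts it measures.
These sizes were chosen so the whole suite runs comfortably on a laptop
core while still exercising every selection branch of the contact cascade.

## Known limitations

* Only the pair families the canned queries rely on are guaranteed; the
  classifier is not a general Leontis–Westhof annotator, and its numeric
  cutoffs are calibrated on constructed fixtures, not on a curated pair
  database.
* Geometric (template + discrepancy cutoff) search and solvent constraints
  are out of scope; backbone suite names and Z\_I/Z\_II classification are
  not computed.
* Hit counts on representative sets are only comparable when the same set
  list is used; the set itself must be supplied as a plain-text
  `PDBID|model|chain` file.
* Annotation is per asymmetric unit; symmetry mates are not expanded.
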