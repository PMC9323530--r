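# zmotif

Lone-pair…π contact annotation and Z-step / Z-turn motif search in RNA 3D
structures.

Z-steps are NpN dinucleotides isostructural to the CpG steps of Z-DNA:
5′-nucleotide *anti* with a C2′-endo sugar, 3′-nucleotide *syn*,
head-to-head riboses, and a lone-pair…π (oxygen…π) contact in which the
O4′ of the 5′-ribose stacks on the 3′-face of the 3′-nucleobase (written
`sO4′3`). The same contact closes the ubiquitous r(UNCG) tetraloops —
Z-turns — and their r(GNNA)/r(CNNG) relatives. `zmotif` makes these
signatures searchable:

* **Contact annotation.** For every ordered nucleotide pair, backbone
  oxygens (OP1, OP2, O2′, O3′, O4′, O5′) are projected onto the partner
  base's reference frame (geometric center of the base heavy atoms;
  total-least-squares plane; signed normal whose positive side is the
  3′-face). A true contact has 2.0 Å < |z| ≤ 3.5 Å with the projection
  inside a ring polygon; "near" contacts extend to |z| ≤ 3.6 Å inside a
  ring, or |z| ≤ 3.5 Å inside the fitted ring ellipse expanded 0.3 Å
  beyond the ring corners. Contacts render as directional strings
  (`sO4′3` / `s3O4′`, near prefix `n`, `n+` matches both).
* **Conformation and pairing.** Glycosidic *syn*/*anti* windows, sugar
  pucker by pseudorotation, hydrogen-bond detection, a reduced
  Leontis–Westhof classifier (cWW, tSW/tWS and near forms), stacking
  faces s33/s35/s53/s55, and the advisory head-to-head ribose call.
* **Symbolic search.** `MotifQuery` objects combine base masks, covalent
  "next" edges, χ/pucker constraints and per-edge pair/stack/contact
  constraints; canned searches cover Z-steps (`findZSteps`),
  Z_anti-steps (`findZAntiSteps`) and the UNNG/GNNA/CNNG Z-turn and
  Z_anti-turn six-node loop queries (`findZTurns`), plus a node-matched
  RMSD similarity matrix over hits (`mutualRMSDMatrix`).
* **Synthetic fixtures.** `buildNucleotide`, `buildZStep`,
  `buildUNCGZTurn`, `buildAFormDuplex`, `buildZHelix` construct
  ground-truth-labelled geometries with exact control of χ and
  pseudorotation, so every annotation rule is testable with no structure
  download.

Structures are read from mmCIF or PDB (`readStructure`, via bio3d), with
the survey occupancy policy applied by `filterAltlocs` (alternate
conformations with occupancy < 1 are ignored).

## Worked example

```r
library(zmotif)

zt <- buildUNCGZTurn()                    # stem-UUCG-stem with planted signature
st <- asRNAStructure(zt$records, "DEMO")

scanLpPi(st)[, c("base_nt", "oxygen_nt", "oxygen_atom", "face", "z", "category")]
#>   base_nt oxygen_nt oxygen_atom face z category
#> 1     5:A       4:A         O4'    3 3     true

classifyBasePair(nucleotides(st)[[2]], nucleotides(st)[[5]])[, c("family", "orientation", "near")]
#>   family orientation  near
#> 1    tSW       trans FALSE

hitTable(findZTurns(st, template = "UNNG", strictness = "strict"))
#>   structure_id model chain                   nodes sequence
#> 1         DEMO     1     A 1:A,2:A,3:A,4:A,5:A,6:A   CUUCGG
```

The one reported contact is the planted CpG Z-step of the loop: the O4′ of
nucleotide 4 sits 3.0 Å over the 3′-face (face 3) of the *syn* guanine 5,
a true (not near) oxygen…π contact, written `sO4′3` from the oxygen side.
The U2•G5 closing pair classifies *trans* Sugar/Watson-Crick, and the
strict six-node UNNG query — sequence mask, tSW closing pair, `sO4′3`
contact and *anti* constraints — returns exactly the planted loop.

A command-line interface wraps the same functions:

```sh
exec/zmotif scan-lppi structure.cif --near --format csv --out contacts.csv
exec/zmotif find-zturns --template UNNG --strictness strict --resolution-max 2.0 *.cif
```

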