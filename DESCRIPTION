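Package: zmotif
Title: Lone-Pair...pi Contact Annotation and Z-Step/Z-Turn Motif Search in RNA 3D Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates lone-pair...pi (oxygen...pi) contacts between backbone
    oxygens and nucleobase faces in RNA 3D structures (mmCIF/PDB), using the
    3'-face/5'-face convention, per-ring fitted and expanded ellipses, and the
    true/near contact bands. On top of the contact annotations it classifies
    glycosidic conformation, sugar pucker, a reduced set of Leontis-Westhof
    base-pair families (cWW, tSW) and base-base stacking faces, and runs
    symbolic constraint searches for Z-steps, Z_anti-steps and
    r(UNNG)/r(GNNA)/r(CNNG) Z-turn and Z_anti-turn loop signatures. Includes a
    synthetic-fixture generator producing idealized ribonucleotides with
    controllable glycosidic angle, sugar pucker and relative placement so that
    every annotation rule is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
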