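# Ideal ribonucleotide reference geometry (heavy atoms, 5'-monophosphate,
# OP3 leaving-group oxygen dropped). Coordinates in Angstrom. Generated from
# standard chemical component definitions; one conformer per base.
# Atom names use the ASCII apostrophe internally; user-facing strings render
# the Unicode prime (see .displayName).
.refNucGeometry <- list(
  A = rbind(
    "P" = c(1.0240, -0.1370, -4.7230),
    "OP1" = c(1.6330, 1.1900, -4.4880),
    "OP2" = c(-0.1830, 0.0050, -5.7780),
    "O5'" = c(0.4560, -0.7200, -3.3340),
    "C5'" = c(-0.5200, 0.2090, -2.8630),
    "C4'" = c(-1.1010, -0.2870, -1.5380),
    "O4'" = c(-0.0640, -0.3830, -0.5380),
    "C3'" = c(-2.1050, 0.7390, -0.9690),
    "O3'" = c(-3.4450, 0.3600, -1.2870),
    "C2'" = c(-1.8740, 0.6840, 0.5580),
    "O2'" = c(-3.0650, 0.2710, 1.2310),
    "C1'" = c(-0.7550, -0.3670, 0.7290),
    "N9" = c(0.1580, 0.0290, 1.8030),
    "C8" = c(1.2650, 0.8130, 1.6720),
    "N7" = c(1.8430, 0.9630, 2.8280),
    "C5" = c(1.1430, 0.2920, 3.7730),
    "C6" = c(1.2900, 0.0910, 5.1560),
    "N6" = c(2.3440, 0.6640, 5.8460),
    "N1" = c(0.3910, -0.6560, 5.7870),
    "C2" = c(-0.6170, -1.2060, 5.1360),
    "N3" = c(-0.7920, -1.0510, 3.8410),
    "C4" = c(0.0560, -0.3200, 3.1260)
  ),
  C = rbind(
    "P" = c(1.0490, -0.0390, -4.0280),
    "OP1" = c(1.6920, 1.2370, -3.6460),
    "OP2" = c(-0.1160, 0.2460, -5.1020),
    "O5'" = c(0.4150, -0.7330, -2.7210),
    "C5'" = c(-0.5460, 0.1810, -2.1930),
    "C4'" = c(-1.1890, -0.4190, -0.9420),
    "O4'" = c(-0.1900, -0.6480, 0.0760),
    "C3'" = c(-2.1780, 0.5830, -0.3070),
    "O3'" = c(-3.5180, 0.2830, -0.7030),
    "C2'" = c(-2.0010, 0.3730, 1.2150),
    "O2'" = c(-3.2280, -0.0590, 1.8060),
    "C1'" = c(-0.9240, -0.7290, 1.3170),
    "N1" = c(-0.0360, -0.4700, 2.4530),
    "C2" = c(0.6520, 0.6830, 2.5140),
    "O2" = c(0.5290, 1.5040, 1.6200),
    "N3" = c(1.4670, 0.9450, 3.5350),
    "C4" = c(1.6200, 0.0700, 4.5200),
    "N4" = c(2.4640, 0.3500, 5.5690),
    "C5" = c(0.9160, -1.1510, 4.4830),
    "C6" = c(0.0870, -1.3990, 3.4420)
  ),
  G = rbind(
    "P" = c(-0.9110, -0.2770, 5.0080),
    "OP1" = c(-1.5980, 1.0220, 4.8440),
    "OP2" = c(0.3250, -0.1050, 6.0250),
    "O5'" = c(-0.3650, -0.7800, 3.5800),
    "C5'" = c(0.5420, 0.2170, 3.1090),
    "C4'" = c(1.1000, -0.2000, 1.7480),
    "O4'" = c(0.0330, -0.3180, 0.7820),
    "C3'" = c(2.0250, 0.8980, 1.1820),
    "O3'" = c(3.3950, 0.5820, 1.4390),
    "C2'" = c(1.7410, 0.8840, -0.3380),
    "O2'" = c(2.9270, 0.5600, -1.0660),
    "C1'" = c(0.6750, -0.2200, -0.5070),
    "N9" = c(-0.2970, 0.1620, -1.5340),
    "C8" = c(-1.4400, 0.8800, -1.3340),
    "N7" = c(-2.0660, 1.0370, -2.4640),
    "C5" = c(-1.3640, 0.4310, -3.4530),
    "C6" = c(-1.5560, 0.2790, -4.8460),
    "O6" = c(-2.5340, 0.7550, -5.3970),
    "N1" = c(-0.6260, -0.4010, -5.5510),
    "C2" = c(0.4590, -0.9340, -4.9230),
    "N2" = c(1.3840, -1.6260, -5.6640),
    "N3" = c(0.6490, -0.8000, -3.6300),
    "C4" = c(-0.2260, -0.1340, -2.8680)
  ),
  U = rbind(
    "P" = c(-1.0300, 0.0470, -4.0370),
    "OP1" = c(-1.6790, -1.2280, -3.6600),
    "OP2" = c(0.1380, -0.2410, -5.1070),
    "O5'" = c(-0.3990, 0.7360, -2.7260),
    "C5'" = c(0.5570, -0.1820, -2.1960),
    "C4'" = c(1.1970, 0.4150, -0.9420),
    "O4'" = c(0.1940, 0.6450, 0.0740),
    "C3'" = c(2.1810, -0.5880, -0.3010),
    "O3'" = c(3.5240, -0.2880, -0.6860),
    "C2'" = c(1.9950, -0.3830, 1.2180),
    "O2'" = c(3.2190, 0.0460, 1.8190),
    "C1'" = c(0.9220, 0.7230, 1.3190),
    "N1" = c(0.0280, 0.4640, 2.4510),
    "C2" = c(-0.6900, -0.6710, 2.4860),
    "O2" = c(-0.5870, -1.4740, 1.5800),
    "N3" = c(-1.5150, -0.9360, 3.5170),
    "C4" = c(-1.6410, -0.0550, 4.5300),
    "O4" = c(-2.3910, -0.2920, 5.4600),
    "C5" = c(-0.8940, 1.1460, 4.5020),
    "C6" = c(-0.0700, 1.3840, 3.4590)
  )
)

# ---- base chemistry tables -------------------------------------------------
# Internal atom names use the ASCII apostrophe; user-facing annotation strings
# use the Unicode prime (see .displayName / .asciiName).

.purines <- c("A", "G")
.pyrimidines <- c("C", "U")
.rnaBases <- c("A", "C", "G", "U")
.dnaResidues <- c("DA", "DC", "DG", "DT")

# Heavy atoms of the base moiety (ring + exocyclic), per base type.
.baseHeavyAtoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

# Ring atoms in cyclic order (polygon vertices). Purines carry two rings;
# ring 1 is the six-membered ring in both cases.
.ringSets <- list(
  A = list(six = c("N1", "C2", "N3", "C4", "C5", "C6"),
           five = c("N9", "C8", "N7", "C5", "C4")),
  G = list(six = c("N1", "C2", "N3", "C4", "C5", "C6"),
           five = c("N9", "C8", "N7", "C5", "C4")),
  C = list(six = c("N1", "C2", "N3", "C4", "C5", "C6")),
  U = list(six = c("N1", "C2", "N3", "C4", "C5", "C6"))
)

# Union of all ring atoms, used e.g. by the altloc occupancy policy and by the
# "annotatable" flag.
.ringAtoms <- function(base) unique(unlist(.ringSets[[base]]))

# Glycosidic nitrogen and the base atom defining chi (O4'-C1'-N9-C4 purines,
# O4'-C1'-N1-C2 pyrimidines).
.glyN <- c(A = "N9", G = "N9", C = "N1", U = "N1")
.chiBaseAtom <- c(A = "C4", G = "C4", C = "C2", U = "C2")

# Stored intra-base vectors fixing the sign of the base normal so that the
# positive normal points toward the 3'-face (see the methods vignette).
.normalRefAtoms <- list(
  A = c("N9", "C4", "C8"), G = c("N9", "C4", "C8"),
  C = c("N1", "C2", "C6"), U = c("N1", "C2", "C6")
)

# Ribose ring in the cyclic/torsion order used by the pseudorotation formulas.
.sugarRing <- c("O4'", "C1'", "C2'", "C3'", "C4'")

# Backbone oxygens eligible as lone-pair...pi donors.
.lpOxygens <- c("OP1", "OP2", "O2'", "O3'", "O4'", "O5'")

.displayName <- function(x) gsub("'", "′", x, fixed = TRUE)
.asciiName <- function(x) gsub("′", "'", x)
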