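# Shared fixtures, built once per test session (some builders run rigid
# placement optimisations and take seconds).

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixtureCache)) {
    val <- switch(name,
      zstep = buildZStep(),
      zstepStacked = buildZStep(stacked = TRUE),
      zstepNear = buildZStep(zOffset = 3.55),
      zantiStep = buildZAntiStep(),
      uncgTurn = buildUNCGZTurn(),
      uncgTurnBroken = buildUNCGZTurn(breakPair = TRUE),
      zhelix = buildZHelix(3L),
      aform = buildAFormDuplex("GACGUC"),
      pairGC = buildBasePair("G", "C", "cWW"),
      pairUG = buildBasePair("U", "G", "tSW"),
      pairGA = buildBasePair("G", "A", "tSW"),
      stop("unknown fixture ", name))
    assign(name, val, envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

fixtureStructure <- function(name, id = toupper(name)) {
  asRNAStructure(fixture(name)$records, structureId = id)
}

# Ideal nucleotides per base at fixed conformation, cached.
idealNt <- function(base, chi = -160, puckerP = 18) {
  key <- sprintf("nt_%s_%g_%g", base, chi, puckerP)
  if (!exists(key, envir = .fixtureCache))
    assign(key, buildNucleotide(base, chi = chi, puckerP = puckerP),
           envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}
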