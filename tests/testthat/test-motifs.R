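test_that("the planted UNCG Z-turn is found by loose and strict queries", {
  st <- fixtureStructure("uncgTurn")
  expect_length(findZTurns(st, "UNNG", "loose"), 1L)
  expect_length(findZTurns(st, "UNNG", "strict"), 1L)
  hit <- hitTable(findZTurns(st, "UNNG", "strict"))
  expect_identical(hit$sequence, "CUUCGG")
  # wrong templates see nothing here
  expect_length(findZTurns(st, "GNNA", "strict"), 0L)
  expect_length(findZTurns(st, "CNNG", "loose"), 0L)
})

test_that("breaking the closing pair suppresses all hits", {
  st <- fixtureStructure("uncgTurnBroken")
  expect_length(findZTurns(st, "UNNG", "loose"), 0L)
  expect_length(findZTurns(st, "UNNG", "strict"), 0L)
})

test_that("an empty structure list yields an empty hit list", {
  q <- motifQuery(c("N", "U", "N", "N", "G", "N"))
  hits <- runQuery(q, list())
  expect_length(hits, 0L)
  expect_identical(nrow(hitTable(hits)), 0L)
})

test_that("the Z-helix yields one Z-step per planted CpG step", {
  st <- fixtureStructure("zhelix")
  hits <- findZSteps(st)
  expect_length(hits, 3L)
  expect_identical(unique(hitTable(hits)$step), "CpG")
  # regular helices are clean negative controls
  expect_length(findZSteps(fixtureStructure("aform")), 0L)
  expect_length(findZTurns(fixtureStructure("aform"), "UNNG"), 0L)
})

test_that("Z-step and Z_anti-step signatures are disjoint", {
  zs <- fixtureStructure("zstep")
  za <- fixtureStructure("zantiStep")
  expect_length(findZSteps(zs), 1L)
  expect_length(findZAntiSteps(zs), 0L)
  expect_length(findZAntiSteps(za), 1L)
  expect_length(findZSteps(za), 0L)
})

test_that("the stack-fallback mode finds the mutually stacked Z-step", {
  st <- fixtureStructure("zstepStacked")
  expect_length(findZSteps(st, mode = "stack_fallback"), 1L)
})

test_that("strict hit sets are subsets of loose hit sets", {
  base <- fixture("uncgTurn")$records
  structs <- lapply(1:5, function(s)
    asRNAStructure(perturbRecords(base, sigma = 0.08, seed = s),
                   structureId = sprintf("PERT%d", s)))
  loose <- findZTurns(structs, "UNNG", "loose")
  strict <- findZTurns(structs, "UNNG", "strict")
  keys <- function(h) paste(hitTable(h)$structure_id, hitTable(h)$nodes)
  expect_true(all(keys(strict) %in% keys(loose)))
})

test_that("strict Z-step hits re-validate their own constraints", {
  st <- fixtureStructure("zhelix")
  hits <- findZSteps(st)
  keymap <- stats::setNames(nucleotides(st),
                            vapply(nucleotides(st), ntKey, character(1L)))
  for (h in seq_len(length(hits))) {
    nodes <- hits@nodeKeys[[h]]
    nt1 <- keymap[[nodes[1L]]]
    nt2 <- keymap[[nodes[2L]]]
    ann <- annotateLpPi(nt2, nt1)   # base = 3'-nt, oxygen owner = 5'-nt
    expect_true(matchLpPiConstraint(ann, "sO4'3"))
    expect_identical(annotateGlycosidic(nt1)$cls, "anti")
    expect_identical(annotateSugarPucker(nt1)$cls, "C2'-endo")
    expect_identical(annotateGlycosidic(nt2)$cls, "syn")
  }
})

test_that("resolution filtering applies to structure metadata", {
  recs <- fixture("uncgTurn")$records
  hi <- asRNAStructure(recs, "HIRES", resolution = 1.9)
  lo <- asRNAStructure(recs, "LORES", resolution = 2.8)
  nores <- asRNAStructure(recs, "NORES")
  hits <- suppressMessages(
    findZTurns(list(hi, lo, nores), "UNNG", resolutionMax = 2.0))
  expect_identical(hitTable(hits)$structure_id, "HIRES")
  expect_message(findZTurns(list(nores), "UNNG", resolutionMax = 2.0),
                 "without a stated resolution")
})

test_that("malformed query constraints error before scanning", {
  expect_error(motifQuery(c("N", "N"),
                          lppiConstraints = list(list(i = 1L, j = 2L,
                                                      spec = "sZ9"))),
               "malformed")
  expect_error(motifQuery(c("N", "N"),
                          pairConstraints = list(list(i = 1L, j = 2L,
                                                      spec = "xWW"))),
               "bad token")
  expect_error(motifQuery(c("N", "Q")), "invalid base mask")
  expect_error(
    motifQuery(c("N", "N"),
               pairConstraints = list(list(i = 1L, j = 3L, spec = "cWW"))),
    "out of range")
})

test_that("pair constraint grammar handles near alternatives and bases", {
  ps <- zmotif:::.parsePairSpec("tSW ntSW UG")
  expect_length(ps$fams, 2L)
  expect_identical(ps$combo, c("U", "G"))
  ps2 <- zmotif:::.parsePairSpec("n+tSW")
  expect_length(ps2$fams, 2L)
  expect_true(any(vapply(ps2$fams, function(f) f$near, logical(1L))))
})

test_that("the CNNG Z_anti-turn template demands cWW, sO4'5 and anti", {
  # the UNCG turn does not satisfy the Z_anti template
  expect_length(findZTurns(fixtureStructure("uncgTurn"), "zanti_CNNG"), 0L)
})

test_that("mutual RMSD matrices behave like a metric on hits", {
  base <- fixture("uncgTurn")$records
  structs <- list(
    asRNAStructure(base, "ORIG"),
    asRNAStructure(lapply(base, rigidMove, R = randomRotation(), t = c(3, 4, 5)),
                   "MOVED"),
    asRNAStructure(perturbRecords(base, sigma = 0.1, seed = 3L), "NOISY"))
  hits <- findZTurns(structs, "UNNG", "loose")
  expect_length(hits, 3L)
  M <- mutualRMSDMatrix(hits, structs)
  expect_identical(dim(M), c(3L, 3L))
  expect_true(isSymmetric(M))
  expect_equal(diag(M), rep(0, 3))
  io <- match(c("ORIG", "MOVED"), hitTable(hits)$structure_id)
  expect_lt(M[io[1L], io[2L]], 1e-6)
  ino <- match("NOISY", hitTable(hits)$structure_id)
  expect_gt(M[io[1L], ino], 0.03)
})

test_that("hit RMSD equals an independent Kabsch oracle", {
  base <- fixture("uncgTurn")$records
  pert <- perturbRecords(base, sigma = 0.1, seed = 9L)
  structs <- list(asRNAStructure(base, "A1"), asRNAStructure(pert, "A2"))
  hits <- findZTurns(structs, "UNNG", "loose")
  expect_length(hits, 2L)
  M <- mutualRMSDMatrix(hits, structs)
  coords <- function(recs) do.call(rbind, lapply(recs, function(nt)
    nt$atoms[intersect(c(zmotif:::.baseHeavyAtoms[[nt$base]], "C1'"),
                       rownames(nt$atoms)), , drop = FALSE]))
  want <- oracleRMSD(coords(base), coords(pert))
  expect_equal(M[1L, 2L], want, tolerance = 1e-6)
  expect_error(mutualRMSDMatrix(findZTurns(structs[1], "UNNG"), structs),
               "at least 2")
})

test_that("survey checks flag CpC steps and a non-CpG mode", {
  st <- fixtureStructure("zhelix")
  res <- checkZStepSurvey(findZSteps(st))
  expect_true(res$modal_is_CpG)
  expect_true(res$no_CpC)
  fake <- findZSteps(st)
  fake@table$step <- c("CpC", "ApA", "ApA")
  w <- testthat::capture_warnings(checkZStepSurvey(fake))
  expect_true(any(grepl("CpC", w)))
  expect_true(any(grepl("modal", w)))
})
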