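test_that("an ideal Watson-Crick G=C carries three hydrogen bonds", {
  pr <- fixture("pairGC")$records
  hb <- detectHBonds(pr[[1L]], pr[[2L]])
  strict <- hb[!hb$near, ]
  expect_gte(nrow(strict), 3L)
  engagedG <- unique(ifelse(strict$donor_side == 1L, strict$donor,
                            strict$acceptor))
  expect_true(all(c("O6", "N1", "N2") %in% engagedG))
  expect_true(all(strict$angle >= 110))
})

test_that("distant bases yield no hydrogen bonds and no pair", {
  nt1 <- idealNt("G")
  nt2 <- idealNt("C")
  nt2$atoms <- sweep(nt2$atoms, 2L, c(10, 0, 0), "+")
  nt2$seq <- 2L
  expect_identical(nrow(detectHBonds(nt1, nt2)), 0L)
  expect_null(classifyBasePair(nt1, nt2))
})

test_that("constructed pairs classify into their intended families", {
  gc <- fixture("pairGC")$records
  p <- classifyBasePair(gc[[1L]], gc[[2L]])
  expect_identical(p$family, "cWW")
  expect_identical(p$orientation, "cis")
  expect_false(p$near)
  expect_false(p$provisional)

  ug <- fixture("pairUG")$records
  q <- classifyBasePair(ug[[1L]], ug[[2L]])
  expect_identical(q$family, "tSW")
  expect_identical(q$orientation, "trans")
  expect_identical(q$edge1, "S")   # uracil engages O2 + 2'-OH
  expect_identical(q$edge2, "W")

  ga <- fixture("pairGA")$records
  r <- classifyBasePair(ga[[1L]], ga[[2L]])
  expect_identical(r$family, "tSW")
})

test_that("classification is symmetric up to edge transposition", {
  ug <- fixture("pairUG")$records
  fwd <- classifyBasePair(ug[[1L]], ug[[2L]])
  rev <- classifyBasePair(ug[[2L]], ug[[1L]])
  expect_identical(rev$family, "tWS")
  expect_identical(rev$orientation, fwd$orientation)
  expect_identical(c(rev$edge1, rev$edge2), c(fwd$edge2, fwd$edge1))
})

test_that("the planted tSW pair of the Z-turn fixture is recovered", {
  recs <- fixture("uncgTurn")$records
  p <- classifyBasePair(recs[[2L]], recs[[5L]])
  expect_identical(p$family, "tSW")
  expect_false(p$near)
})

test_that("parallel offset bases stack with the constructed faces", {
  nt1 <- idealNt("A")
  fr1 <- baseFrame(nt1)
  nt2 <- idealNt("G")
  nt2$seq <- 2L
  fr2 <- baseFrame(nt2)
  # put nt2's center 3.4 along nt1's 3'-face normal, planes parallel,
  # nt2's own normal pointing back at nt1 (its 3'-face towards nt1): s35
  ax <- zmotif:::.cross(fr2@normal, -fr1@normal)
  R <- if (sqrt(sum(ax^2)) < 1e-9) diag(3) else
    zmotif:::.rotAxis(ax, zmotif:::.angle3(fr2@center + fr2@normal, fr2@center,
                                           fr2@center - fr1@normal))
  nt2$atoms <- sweep(sweep(nt2$atoms, 2L, fr2@center) %*% t(R), 2L,
                     fr1@center + 3.4 * fr1@normal, "+")
  s <- classifyStacking(nt1, nt2)
  expect_identical(s$faces, "s33")
  expect_false(s$near)
  expect_equal(s$z_offset, 3.4, tolerance = 0.2)
  # same placement with parallel (instead of opposed) normals: the partner
  # now presents its 5'-face, i.e. the regular-helix s35 arrangement
  nt2p <- idealNt("G")
  nt2p$seq <- 2L
  fr2p <- baseFrame(nt2p)
  ax2 <- zmotif:::.cross(fr2p@normal, fr1@normal)
  R2 <- if (sqrt(sum(ax2^2)) < 1e-9) diag(3) else
    zmotif:::.rotAxis(ax2, zmotif:::.angle3(fr2p@center + fr2p@normal,
                                            fr2p@center,
                                            fr2p@center + fr1@normal))
  nt2p$atoms <- sweep(sweep(nt2p$atoms, 2L, fr2p@center) %*% t(R2), 2L,
                      fr1@center + 3.4 * fr1@normal, "+")
  sf <- classifyStacking(nt1, nt2p)
  expect_identical(sf$faces, "s35")
})

test_that("coplanar side-by-side bases do not stack", {
  nt1 <- idealNt("C")
  fr1 <- baseFrame(nt1)
  nt2 <- idealNt("C")
  nt2$seq <- 2L
  nt2$atoms <- sweep(nt2$atoms, 2L, 6 * fr1@basis[, 1L], "+")
  expect_null(classifyStacking(nt1, nt2))
})

test_that("the stacked Z-step arrangement classifies s53", {
  recs <- fixture("zstepStacked")$records
  s <- classifyStacking(recs[[1L]], recs[[2L]])
  expect_identical(s$faces, "s53")
  expect_false(s$near)
  # and it still carries the true sO4'3 contact
  df <- scanLpPi(asRNAStructure(recs))
  expect_identical(df$oxygen_first, "sO4′3")
  expect_identical(df$category, "true")
})

test_that("A-form duplex steps pair cWW with no tSW false positives", {
  st <- fixtureStructure("aform")
  pp <- suppressMessages(annotatePairs(st))
  n <- 6L
  for (i in seq_len(n)) {
    row <- pp[pp$nt1 == sprintf("%d:A", i) & pp$nt2 == sprintf("%d:B", n - i + 1L), ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$family, "cWW")
    expect_false(row$near)
  }
  expect_false(any(pp$family %in% c("tSW", "tWS") & !pp$provisional))
  expect_false(any(pp$family %in% c("tSW", "tWS")))
})

test_that("randomized near-contact geometries match a brute-force bond scan", {
  set.seed(77)
  donors <- zmotif:::.donorsOf
  acceptors <- zmotif:::.acceptorsOf
  for (i in 1:40) {
    nt1 <- idealNt(sample(c("A", "C", "G", "U"), 1L))
    nt2 <- rigidMove(idealNt(sample(c("A", "C", "G", "U"), 1L)),
                     t = rnorm(3, 0, 4))
    nt2$seq <- 2L
    got <- detectHBonds(nt1, nt2)
    want <- 0L
    for (side in 1:2) {
      don <- if (side == 1L) nt1 else nt2
      acc <- if (side == 1L) nt2 else nt1
      dl <- donors(don)
      for (dAtom in intersect(names(dl), rownames(don$atoms))) {
        ants <- intersect(dl[[dAtom]], rownames(don$atoms))
        if (!length(ants)) next
        for (aAtom in intersect(acceptors(acc), rownames(acc$atoms))) {
          dd <- sqrt(sum((don$atoms[dAtom, ] - acc$atoms[aAtom, ])^2))
          if (dd > 4.0 || dd < 1e-6) next
          ang <- max(vapply(ants, function(an) zmotif:::.angle3(
            don$atoms[an, ], don$atoms[dAtom, ], acc$atoms[aAtom, ]),
            numeric(1L)))
          if (ang >= 110) want <- want + 1L
        }
      }
    }
    expect_identical(nrow(got), want)
  }
})
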