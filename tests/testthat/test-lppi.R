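params <- lpPiParameters()

test_that("axial placements fall in the documented contact bands", {
  nt <- idealNt("G")
  fr <- baseFrame(nt)
  ctr <- fr@center + fr@basis %*% colMeans(fr@rings[[1L]]@poly)
  place <- function(z) oxygenProbe(list(`O4'` = as.numeric(ctr + z * fr@normal)))
  ann <- annotateLpPi(nt, place(3.0), frame = fr, params = params)
  expect_identical(ann$category, "true")
  expect_identical(ann$face, 3L)
  expect_identical(ann$oxygen_first, "sO4′3")
  expect_identical(ann$base_first, "s3O4′")

  nearAnn <- annotateLpPi(nt, place(3.55), frame = fr, params = params)
  expect_identical(nearAnn$category, "near")
  expect_identical(nearAnn$oxygen_first, "nsO4′3")

  expect_identical(annotateLpPi(nt, place(-3.0), frame = fr,
                                params = params)$face, 5L)
  # in-plane exclusion: |z| = 1.5 is not a contact
  expect_null(annotateLpPi(nt, place(1.5), frame = fr, params = params))
  # the boundary |z| = 3.5 still belongs to the true band (placed a hair
  # inside so that frame arithmetic cannot round the probe across it)
  expect_identical(annotateLpPi(nt, place(3.5 - 1e-9), frame = fr,
                                params = params)$category, "true")
  expect_null(annotateLpPi(nt, place(3.7), frame = fr, params = params))
})

test_that("among in-ring oxygens the smallest |z| wins", {
  nt <- idealNt("G")
  fr <- baseFrame(nt)
  ctr <- fr@center + fr@basis %*% colMeans(fr@rings[[1L]]@poly)
  probe <- oxygenProbe(list(OP1 = as.numeric(ctr + 3.2 * fr@normal),
                            OP2 = as.numeric(ctr + 0.3 * fr@basis[, 1L] +
                                               2.9 * fr@normal)))
  ann <- annotateLpPi(nt, probe, frame = fr, params = params)
  expect_identical(ann$oxygen_atom, "OP2")
  expect_equal(ann$z, 2.9, tolerance = 1e-9)
})

test_that("the lateral near case picks the projection closest to the center", {
  nt <- idealNt("U")
  fr <- baseFrame(nt)
  ell <- fr@rings[[1L]]
  edge <- ell@center2d + c(ell@semiAxes[1L] + 0.12, 0)
  p1 <- as.numeric(fr@center + fr@basis %*% edge + 3.0 * fr@normal)
  edge2 <- ell@center2d + c(ell@semiAxes[1L] + 0.2, 0)
  p2 <- as.numeric(fr@center + fr@basis %*% edge2 + 2.8 * fr@normal)
  ann <- annotateLpPi(nt, oxygenProbe(list(`O5'` = p1, `O3'` = p2)),
                      frame = fr, params = params)
  expect_identical(ann$category, "near")
  expect_identical(ann$oxygen_atom, "O5'")
})

test_that("randomized placements agree with the brute-force oracle", {
  set.seed(101)
  for (base in c("A", "C", "G", "U")) {
    nt <- idealNt(base)
    fr <- baseFrame(nt)
    for (i in 1:500) {
      k <- sample(1:3, 1L)
      names <- sample(zmotif:::.lpOxygens, k)
      coords <- lapply(seq_len(k), function(j) as.numeric(
        fr@center + fr@basis %*% runif(2, -3.2, 3.2) +
          runif(1, -4, 4) * fr@normal))
      names(coords) <- names
      probe <- oxygenProbe(coords)
      got <- annotateLpPi(nt, probe, frame = fr, params = params)
      want <- oracleAnnotate(fr, probe, params)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got$oxygen_atom, want$atom)
        expect_identical(got$category, want$category)
        expect_equal(got$z, want$z, tolerance = 1e-9)
      }
    }
  }
})

test_that("shrinking the true band never adds true annotations", {
  st <- fixtureStructure("zstep")
  wide <- scanLpPi(st, params = params)
  narrow <- scanLpPi(st, params = lpPiParameters(zMaxTrue = 3.2, zMaxNear = 3.3))
  expect_lte(sum(narrow$category == "true"), sum(wide$category == "true"))
  # and enabling near never removes true annotations
  trueOnly <- scanLpPi(st, params = params, near = FALSE)
  expect_true(all(trueOnly$oxygen_first %in% wide$oxygen_first))
})

test_that("scan with near splits into disjoint true and near sets", {
  recs <- c(fixture("zstep")$records,
            lapply(fixture("zstepNear")$records, function(nt) {
              nt$chain <- "C"; nt
            }))
  st <- asRNAStructure(recs, "MIX")
  all_ <- scanLpPi(st, near = TRUE)
  trues <- scanLpPi(st, near = FALSE)
  key <- function(df) paste(df$base_nt, df$oxygen_nt)
  expect_setequal(key(trues), key(all_[all_$category == "true", ]))
  expect_length(intersect(key(trues), key(all_[all_$category == "near", ])), 0L)
})

test_that("reflecting through the base plane swaps faces 3 and 5 only", {
  nt <- idealNt("G")
  fr <- baseFrame(nt)
  set.seed(55)
  for (i in 1:50) {
    p <- as.numeric(fr@center + fr@basis %*% runif(2, -2, 2) +
                      runif(1, 2.2, 3.4) * fr@normal)
    mirror <- as.numeric(p - 2 * sum((p - fr@center) * fr@normal) * fr@normal)
    a1 <- annotateLpPi(nt, oxygenProbe(list(`O2'` = p)), frame = fr,
                       params = params)
    a2 <- annotateLpPi(nt, oxygenProbe(list(`O2'` = mirror)), frame = fr,
                       params = params)
    expect_identical(is.null(a1), is.null(a2))
    if (!is.null(a1)) {
      expect_identical(a1$face + a2$face, 8L)   # {3, 5}
      expect_identical(a1$category, a2$category)
      expect_equal(a1$z, -a2$z, tolerance = 1e-9)
    }
  }
})

test_that("the two directional strings always mirror the same contact", {
  df <- scanLpPi(fixtureStructure("zhelix"))
  for (i in seq_len(nrow(df))) {
    oxy <- zmotif:::.displayName(df$oxygen_atom[i])
    pre <- if (df$category[i] == "near") "n" else ""
    expect_identical(df$base_first[i], sprintf("%ss%d%s", pre, df$face[i], oxy))
    expect_identical(df$oxygen_first[i], sprintf("%ss%s%d", pre, oxy, df$face[i]))
  }
})

test_that("an empty record list scans to an empty table", {
  df <- scanLpPi(list())
  expect_identical(nrow(df), 0L)
  expect_identical(colnames(df)[1:4],
                   c("structure_id", "model", "base_nt", "oxygen_nt"))
})

test_that("constraint strings parse, expand and match as documented", {
  ann <- list(category = "true", face = 3L, oxygen_atom = "O4'")
  expect_true(matchLpPiConstraint(ann, "sO"))
  expect_true(matchLpPiConstraint(ann, "sO4'3"))
  expect_true(matchLpPiConstraint(ann, "s3O4′"))   # Unicode prime accepted
  expect_false(matchLpPiConstraint(ann, "sO4'5"))
  expect_false(matchLpPiConstraint(ann, "sOP"))
  expect_false(matchLpPiConstraint(ann, "nsO4'3"))
  expect_true(matchLpPiConstraint(ann, "n+sO4'3"))

  nearAnn <- list(category = "near", face = 3L, oxygen_atom = "O4'")
  expect_false(matchLpPiConstraint(nearAnn, "sO4'3"))
  expect_true(matchLpPiConstraint(nearAnn, "n+sO4'3"))
  expect_true(matchLpPiConstraint(nearAnn, "nsO4'3"))

  op <- list(category = "true", face = 5L, oxygen_atom = "OP1")
  expect_true(matchLpPiConstraint(op, "sOP"))
  expect_true(matchLpPiConstraint(op, "sO5"))
  expect_false(matchLpPiConstraint(op, "sO3"))

  p <- parseLpPiConstraint("s3O")
  expect_identical(p$direction, "base_first")
  expect_identical(p$face, 3L)
  expect_length(p$oxygens, 6L)
})

test_that("malformed constraints fail with a position", {
  expect_error(parseLpPiConstraint("xO4'3"), "position 1")
  expect_error(parseLpPiConstraint("sX4"), "position 2")
  expect_error(parseLpPiConstraint("s3O4'3"), "position 6")
  expect_error(parseLpPiConstraint("sO4'9"), "position 5")
  err <- tryCatch(parseLpPiConstraint("sQ"), condition = identity)
  expect_s3_class(err, "zmotifParseError")
})
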