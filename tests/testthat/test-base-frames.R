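test_that("a base flattened into the xy-plane has normal (0, 0, +1)", {
  for (base in c("A", "C", "G", "U")) {
    nt <- idealNt(base)
    fr <- baseFrame(nt)
    # re-express the base atoms in frame coordinates: in-plane -> (x, y),
    # normal -> +z; the stored sign convention must then give +z back
    heavy <- intersect(rownames(nt$atoms), zmotif:::.baseHeavyAtoms[[base]])
    rel <- sweep(nt$atoms[heavy, , drop = FALSE], 2L, fr@center)
    flat <- cbind(rel %*% fr@basis[, 1L], rel %*% fr@basis[, 2L], 0)
    rownames(flat) <- heavy
    fr2 <- baseFrame(nucleotideRecord(base, flat))
    expect_equal(fr2@normal, c(0, 0, 1), tolerance = 1e-9)
  }
})

test_that("the fitted plane beats every 3-ring-atom plane on RMS distance", {
  set.seed(7)
  for (base in c("A", "U")) {
    nt <- idealNt(base)
    nt$atoms <- nt$atoms + matrix(rnorm(length(nt$atoms), 0, 0.05),
                                  nrow(nt$atoms), 3L)
    heavy <- intersect(rownames(nt$atoms), zmotif:::.baseHeavyAtoms[[base]])
    X <- nt$atoms[heavy, , drop = FALSE]
    fr <- baseFrame(nt)
    dBest <- planeDist(X, fr@center, fr@normal)
    combs <- utils::combn(seq_len(nrow(X)), 3L)
    for (k in seq_len(ncol(combs))) {
      tri <- X[combs[, k], ]
      n <- zmotif:::.cross(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
      if (sqrt(sum(n^2)) < 1e-8) next
      expect_lte(dBest, planeDist(X, tri[1L, ], n / sqrt(sum(n^2))) + 1e-12)
    }
  }
})

test_that("the base center is the unweighted mean of the base heavy atoms", {
  nt <- idealNt("U")
  heavy <- zmotif:::.baseHeavyAtoms$U
  expect_length(heavy, 8L)
  fr <- baseFrame(nt)
  expect_equal(fr@center, colMeans(nt$atoms[heavy, ]), tolerance = 1e-12)
})

test_that("ellipse fitting recovers circles and exact ellipses", {
  th <- seq(0, 2 * pi, length.out = 7L)[-7L]
  circ <- fitRingEllipse(cbind(1.4 * cos(th), 1.4 * sin(th)))
  expect_equal(circ@semiAxes, c(1.4, 1.4), tolerance = 1e-6)

  a <- 1.5; b <- 1.3; phi <- 0.4; ctr <- c(0.3, -0.2)
  pts <- t(vapply(th, function(t) {
    p <- c(a * cos(t), b * sin(t))
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)
    as.numeric(R %*% p) + ctr
  }, numeric(2L)))
  ell <- fitRingEllipse(pts)
  expect_equal(ell@semiAxes, c(a, b), tolerance = 1e-6)
  expect_equal(ell@center2d, ctr, tolerance = 1e-6)
  expect_equal(ell@orientation %% pi, phi, tolerance = 1e-6)
  expect_lt(ell@residual, 1e-6)

  expect_error(fitRingEllipse(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("standard base rings have small ellipse eccentricity (a/b < 1.3)", {
  for (base in c("A", "C", "G", "U")) {
    fr <- baseFrame(idealNt(base))
    for (e in fr@rings)
      expect_lt(e@semiAxes[1L] / e@semiAxes[2L], 1.3)
  }
})

test_that("frame projection is an exact orthonormal decomposition", {
  set.seed(11)
  fr <- baseFrame(idealNt("G"))
  expect_equal(projectOntoFrame(fr, fr@center + 3 * fr@normal),
               c(x = 0, y = 0, z = 3), tolerance = 1e-9)
  expect_equal(projectOntoFrame(fr, fr@center - 3 * fr@normal)[["z"]], -3,
               tolerance = 1e-9)
  for (i in 1:25) {
    p <- rnorm(3, 0, 8)
    v <- projectOntoFrame(fr, p)
    rec <- fr@center + v[["x"]] * fr@basis[, 1L] + v[["y"]] * fr@basis[, 2L] +
      v[["z"]] * fr@normal
    expect_equal(rec, p, tolerance = 1e-9)
  }
})

test_that("projection membership equals the point-in-polygon/conic oracle", {
  set.seed(23)
  for (base in c("A", "C", "G", "U")) {
    fr <- baseFrame(idealNt(base))
    xs <- cbind(runif(2000, -4, 4), runif(2000, -4, 4))
    for (i in seq_len(nrow(xs))) {
      got <- locateProjection(fr, xs[i, ])$status
      expect_identical(got, oracleLocate(fr, xs[i, ]))
    }
  }
  # the trivial anchors
  frG <- baseFrame(idealNt("G"))
  centroid <- colMeans(frG@rings[[1L]]@poly)
  expect_identical(locateProjection(frG, centroid)$status, "inside_ring")
  expect_identical(locateProjection(frG, c(10, 0))$status, "outside")
})

test_that("ring membership nests inside expanded-ellipse membership", {
  set.seed(31)
  fr <- baseFrame(idealNt("A"))
  xs <- cbind(runif(3000, -3, 3), runif(3000, -3, 3))
  for (i in seq_len(nrow(xs))) {
    st <- locateProjection(fr, xs[i, ])
    if (st$status != "inside_ring") next
    e <- fr@rings[[st$ring]]
    expect_true(zmotif:::.inEllipse(matrix(xs[i, ], 1L), e,
                                    zmotif:::.expansionFactor(e)))
  }
})

test_that("the normal sign convention is invariant under rigid motion", {
  set.seed(5)
  nt <- idealNt("C")
  fr0 <- baseFrame(nt)
  for (i in 1:20) {
    R <- randomRotation()
    moved <- rigidMove(nt, R)
    fr <- baseFrame(moved)
    expect_equal(fr@normal, as.numeric(R %*% fr0@normal), tolerance = 1e-9)
  }
})

test_that("atom input order never changes the face assignment", {
  set.seed(13)
  nt <- idealNt("G")
  fr0 <- baseFrame(nt)
  for (i in 1:10) {
    shuf <- nt
    shuf$atoms <- shuf$atoms[sample(nrow(shuf$atoms)), , drop = FALSE]
    shuf$occ <- shuf$occ[rownames(shuf$atoms)]
    fr <- baseFrame(shuf)
    expect_equal(fr@normal, fr0@normal, tolerance = 1e-9)
    expect_equal(fr@center, fr0@center, tolerance = 1e-9)
  }
})

test_that("a missing ring atom suppresses the frame with a warning", {
  nt <- idealNt("G")
  nt$atoms <- nt$atoms[setdiff(rownames(nt$atoms), "N7"), ]
  expect_warning(fr <- baseFrame(nt), "missing ring atom")
  expect_null(fr)
  expect_false(isAnnotatable(nt))
})
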