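# Synthetic ground-truth fixtures: idealized ribonucleotides with
# controllable glycosidic angle, sugar pucker and relative placement, plus
# multi-nucleotide builders (Z-step, Z_anti-step, UNCG Z-turn, A-form duplex,
# Z-helix). Fixtures exercise the geometric definitions exactly; they are not
# meant to be stereochemically perfect.

# ---- rigid-transform helpers ----------------------------------------------

.tfApply <- function(tf, X) sweep(X %*% t(tf$R), 2L, tf$t, "+")
.tfCompose <- function(A, B) list(R = A$R %*% B$R,
                                  t = as.numeric(A$R %*% B$t) + A$t)
.tfInverse <- function(tf) list(R = t(tf$R), t = as.numeric(-t(tf$R) %*% tf$t))
.tfIdentity <- function() list(R = diag(3), t = c(0, 0, 0))

.applyTfRecord <- function(nt, tf) { nt$atoms <- .tfApply(tf, nt$atoms); nt }

# 6-parameter chart (rotation degrees, translation Angstrom) about a pivot.
.tfFromParams <- function(p, pivot) {
  R <- .rotEuler(p[1:3])
  list(R = R, t = as.numeric(pivot - R %*% pivot + p[4:6]))
}

# Deterministic rigid placement: minimise `objective(tf)` over rigid motions,
# restarting from a fixed set of initial orientations.
.placeRigid <- function(objective, pivot, inits = NULL, maxit = 3000) {
  if (is.null(inits))
    inits <- list(rep(0, 6), c(180, 0, 0, 0, 0, 0), c(0, 180, 0, 0, 0, 0),
                  c(0, 0, 180, 0, 0, 0), c(90, 90, 0, 0, 0, 0))
  best <- NULL
  for (p0 in inits) {
    fit <- stats::optim(p0, function(p) objective(.tfFromParams(p, pivot)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       parscale = c(30, 30, 30, 2, 2, 2)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(tf = .tfFromParams(best$par, pivot), value = best$value)
}

# Soft minimum-distance penalty between two coordinate sets.
.apartPenalty <- function(A, B, minDist) {
  if (!nrow(A) || !nrow(B)) return(0)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  sum(pmax(0, minDist - d)^2)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# ---- sugar ring generation -------------------------------------------------

# Measure (P, amplitude) of a bare 5 x 3 ring coordinate matrix (rows in
# .sugarRing order).
.ringPucker <- function(X) {
  tor <- function(i, j, k, l) .torsion(X[i, ], X[j, ], X[k, ], X[l, ])
  nu <- c(tor(5, 1, 2, 3), tor(1, 2, 3, 4), tor(2, 3, 4, 5),
          tor(3, 4, 5, 1), tor(4, 5, 1, 2))
  num <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  den <- 2 * nu[3L] * (.SIN36 + .SIN72)
  P <- atan2(num, den) * 180 / pi
  if (P < 0) P <- P + 360
  c(P = P, amplitude = nu[3L] / cos(P * pi / 180))
}

# Ring coordinates with exactly the requested Altona-Sundaralingam phase and
# amplitude: pentagon + Cremer-Pople-style out-of-plane displacements
# (q, phi), solved by 2-D Newton iteration on the measured (P, amplitude).
.ringFromPucker <- function(P, amplitude, bond = 1.45) {
  r <- bond / (2 * .SIN36)
  theta <- 2 * pi * (0:4) / 5
  flat <- cbind(r * cos(theta), r * sin(theta), 0)
  rownames(flat) <- .sugarRing
  if (abs(amplitude) < 1e-9) return(flat)
  ring <- function(q, phi) {
    X <- flat
    X[, 3L] <- sqrt(2 / 5) * q * cos(phi + 4 * pi * (0:4) / 5)
    X
  }
  target <- c(amplitude * cos(P * pi / 180), amplitude * sin(P * pi / 180))
  resid <- function(par) {
    m <- .ringPucker(ring(par[1L], par[2L]))
    c(m[["amplitude"]] * cos(m[["P"]] * pi / 180),
      m[["amplitude"]] * sin(m[["P"]] * pi / 180)) - target
  }
  # coarse phase scan for a starting point
  q0 <- amplitude / 102
  phis <- seq(0, 2 * pi, length.out = 25L)[-25L]
  sc <- vapply(phis, function(ph) sum(resid(c(q0, ph))^2), numeric(1L))
  par <- c(q0, phis[which.min(sc)])
  for (it in 1:60) {
    f <- resid(par)
    if (sum(f^2) < 1e-22) break
    h <- 1e-6
    J <- cbind((resid(par + c(h, 0)) - f) / h, (resid(par + c(0, h)) - f) / h)
    par <- par - as.numeric(solve(J, f))
  }
  ring(par[1L], par[2L])
}

# ---- single-nucleotide builder --------------------------------------------

#' Build an idealized ribonucleotide
#'
#' Standard base geometry (embedded reference table, one conformer per base)
#' attached to a ribose generated at the requested pseudorotation phase and
#' amplitude; the glycosidic torsion chi is set exactly by rotation about the
#' glycosidic bond. Measuring chi and (P, amplitude) on the result recovers
#' the inputs to numerical precision, which is what makes the conformation
#' annotators testable by round trip.
#'
#' @param base one of A, C, G, U.
#' @param chi glycosidic torsion in degrees.
#' @param puckerP pseudorotation phase in degrees.
#' @param amplitude pucker amplitude in degrees (default 40).
#' @param chain,seq,icode,model,structureId residue identity.
#' @return a \code{NucleotideRecord}.
#' @examples
#' nt <- buildNucleotide("G", chi = 60, puckerP = 162)
#' annotateSugarPucker(nt)$cls
#' @export
buildNucleotide <- function(base, chi = -160, puckerP = 18, amplitude = 40,
                            chain = "A", seq = 1L, icode = "", model = 1L,
                            structureId = "FIXTURE") {
  stopifnot(base %in% .rnaBases)
  tmpl <- .refNucGeometry[[base]]
  newRing <- .ringFromPucker(puckerP, amplitude)
  oldRing <- tmpl[.sugarRing, , drop = FALSE]
  remap <- function(group, anchor, nb1, nb2) {
    Fo <- .localFrame(tmpl[anchor, ], tmpl[nb1, ], tmpl[nb2, ])
    Fn <- .localFrame(newRing[anchor, ], newRing[nb1, ], newRing[nb2, ])
    rel <- sweep(tmpl[group, , drop = FALSE], 2L, tmpl[anchor, ])
    sweep((rel %*% Fo) %*% t(Fn), 2L, newRing[anchor, ], "+")
  }
  baseAtoms <- .baseHeavyAtoms[[base]]
  parts <- rbind(
    newRing,
    remap(baseAtoms, "C1'", "O4'", "C2'"),
    remap("O2'", "C2'", "C1'", "C3'"),
    remap("O3'", "C3'", "C2'", "C4'"),
    remap(c("C5'", "O5'", "P", "OP1", "OP2"), "C4'", "C3'", "O4'"))
  nt <- nucleotideRecord(base, parts, chain = chain, seq = seq, icode = icode,
                         model = model, structureId = structureId)
  # set chi exactly by rotating the base about the glycosidic bond; the
  # rotation sense is probed with a 1-degree trial rotation
  nN <- .glyN[[base]]
  axis <- .atomXYZ(nt, nN) - .atomXYZ(nt, "C1'")
  pivot <- .atomXYZ(nt, nN)
  spin <- function(nt, theta) {
    R <- .rotAxis(axis, theta)
    nt$atoms[baseAtoms, ] <- sweep(sweep(nt$atoms[baseAtoms, , drop = FALSE],
                                         2L, pivot) %*% t(R), 2L, pivot, "+")
    nt
  }
  wrap <- function(a) ((a + 180) %% 360) - 180
  g0 <- annotateGlycosidic(nt)$chi
  s <- sign(wrap(annotateGlycosidic(spin(nt, 1))$chi - g0))
  nt <- spin(nt, s * wrap(chi - g0))
  nt
}

#' Add isotropic Gaussian coordinate noise to records
#'
#' @param records list of nucleotide records.
#' @param sigma per-atom, per-coordinate standard deviation (Angstrom).
#' @param seed RNG seed; identical (records, sigma, seed) give identical
#'   output.
#' @return perturbed records.
#' @export
perturbRecords <- function(records, sigma, seed = 1L) {
  if (sigma <= 0) return(records)
  .withSeed(seed, lapply(records, function(nt) {
    nt$atoms <- nt$atoms + matrix(stats::rnorm(length(nt$atoms), 0, sigma),
                                  nrow(nt$atoms), 3L)
    nt
  }))
}

# Snap each P(i+1) (with its OP1/OP2) onto O3'(i) at covalent distance, in
# record order. Guarantees the "next" adjacency that motif queries rely on.
.snapBackbone <- function(records, bond = 1.55) {
  for (i in seq_len(length(records) - 1L)) {
    o3 <- .atomXYZ(records[[i]], "O3'")
    p <- .atomXYZ(records[[i + 1L]], "P")
    if (is.null(o3) || is.null(p)) next
    shift <- (o3 + bond * .unit(p - o3)) - p
    for (a in intersect(c("P", "OP1", "OP2"), rownames(records[[i + 1L]]$atoms)))
      records[[i + 1L]]$atoms[a, ] <- records[[i + 1L]]$atoms[a, ] + shift
  }
  records
}

# ---- Z-step ----------------------------------------------------------------

# Canonical Z-step in the build frame of the 3'-nucleotide: returns the two
# records plus the transform applied to the 5'-nucleotide. The default
# arrangement places the O4' over the six-ring centroid with head-to-head
# riboses; `stacked = TRUE` instead slides the O4' toward the outer edge of
# the six-ring and drapes the 5'-base over the five-ring region so that the
# mutual center-over-ellipse s53 stacking criterion holds as well (both
# arrangements carry the same sO4'3 contact).
.canonicalZStep <- function(base5 = "C", base3 = "G", zOffset = 3.0,
                            xyOffset = c(0, 0), face = 3L,
                            chi5 = -160, chi3 = 60,
                            pucker5 = 162, pucker3 = 18, stacked = FALSE) {
  nt3 <- buildNucleotide(base3, chi = chi3, puckerP = pucker3, seq = 2L)
  nt5 <- buildNucleotide(base5, chi = chi5, puckerP = pucker5, seq = 1L)
  fr <- baseFrame(nt3)
  ctroid <- colMeans(fr@rings[[1L]]@poly)   # six-ring centroid, in-plane
  away <- if (length(fr@rings) > 1L) {
    v <- fr@rings[[1L]]@center2d - fr@rings[[2L]]@center2d
    v / .vnorm(c(v, 0))
  } else c(1, 0)
  if (stacked) {
    if (face != 3L) stop("stacked arrangement is built for face 3")
    xyOffset <- xyOffset + 1.05 * away
  }
  xy <- ctroid + xyOffset
  sgn <- if (face == 3L) 1 else -1
  target <- as.numeric(fr@center + fr@basis %*% xy + sgn * zOffset * fr@normal)
  pivot <- .atomXYZ(nt5, "O4'")
  base5Atoms <- .baseHeavyAtoms[[base5]]
  p3 <- .atomXYZ(nt3, "P")
  u3 <- .unit(.atomXYZ(nt3, "C1'") - .atomXYZ(nt3, "O4'"))
  ring5w <- if (length(fr@rings) > 1L)
    as.numeric(fr@center + fr@basis %*% (fr@rings[[2L]]@center2d - 1.0 * away))
  else fr@center
  obj <- function(tf) {
    # keep O4' exactly on target by composing with a final translation
    tf$t <- tf$t + (target - as.numeric(tf$R %*% pivot + tf$t))
    at <- .tfApply(tf, nt5$atoms)
    gap <- (.vnorm(at["O3'", ] - p3) - 1.6)^2
    u5 <- .unit(at["C1'", ] - at["O4'", ])
    hh <- (sum(u5 * u3) + 1)^2
    clash <- .apartPenalty(at[setdiff(rownames(at), "O4'"), , drop = FALSE],
                           nt3$atoms, if (stacked) 2.7 else 2.8)
    oth <- setdiff(intersect(.lpOxygens, rownames(at)), "O4'")
    off <- sum(pmax(0, (if (stacked) 4.2 else 5) -
                      sqrt(rowSums(sweep(at[oth, , drop = FALSE],
                                         2L, fr@center)^2)))^2)
    bc <- colMeans(at[base5Atoms, , drop = FALSE])
    if (!stacked) {
      away5 <- .apartPenalty(at[base5Atoms, , drop = FALSE],
                             nt3$atoms[.baseHeavyAtoms[[base3]], , drop = FALSE],
                             5.5)
      return(gap + 2 * hh + clash + away5 + off)
    }
    # mutual stacking terms: 5'-base center over the 3'-base five-ring flank
    # on the contacted face, 3'-base center inside the 5'-base ellipse
    z1 <- sum((bc - fr@center) * fr@normal)
    v5 <- bc - ring5w
    lat1 <- .vnorm(v5 - sum(v5 * fr@normal) * fr@normal)
    s1 <- 3 * max(0, 2.6 - z1)^2 + max(0, z1 - 3.2)^2 + lat1^2
    nt5p <- nt5; nt5p$atoms <- at
    fr5 <- baseFrame(nt5p)
    pj <- projectOntoFrame(fr5, fr@center)
    lat2 <- .vnorm(pj[c("x", "y")] - fr5@rings[[1L]]@center2d)
    s2 <- 3 * max(0, pj[["z"]] + 2.6)^2 + max(0, -pj[["z"]] - 4.2)^2 +
      2 * (lat2 - 0.6)^2
    0.1 * gap + clash + 5 * s1 + 5 * s2 + off
  }
  # constructive initialisations: swing the 5'-base toward its target region,
  # then spin about that direction
  vOld <- colMeans(nt5$atoms[base5Atoms, , drop = FALSE]) - pivot
  tf0s <- if (stacked) {
    vWant <- ring5w + 2.8 * fr@normal - target
    ax <- .cross(.unit(vOld), .unit(vWant))
    R0 <- if (.vnorm(ax) < 1e-8) diag(3) else
      .rotAxis(ax, .angle3(pivot + vOld, pivot, pivot + vWant))
    lapply(seq(0, 330, by = 30), function(spin) {
      Ri <- .rotAxis(vWant, spin) %*% R0
      list(R = Ri, t = as.numeric(target - Ri %*% pivot))
    })
  } else {
    lapply(list(c(0, 0, 0), c(180, 0, 0), c(0, 180, 0), c(0, 0, 180),
                c(90, 90, 0)), function(r) {
      Ri <- .rotEuler(r)
      list(R = Ri, t = as.numeric(target - Ri %*% pivot))
    })
  }
  best <- NULL
  safe <- function(tf) {
    v <- tryCatch(obj(tf), error = function(e) NA_real_)
    if (!is.finite(v)) 1e6 else v
  }
  for (tf0 in tf0s) {
    fit <- stats::optim(rep(0, 6), function(p)
      safe(.tfCompose(.tfFromParams(p, target), tf0)),
      method = "Nelder-Mead",
      control = list(maxit = 6000, reltol = 1e-12,
                     parscale = c(30, 30, 30, 2, 2, 2)))
    if (is.null(best) || fit$value < best$fit$value)
      best <- list(fit = fit, tf0 = tf0)
  }
  tf <- .tfCompose(.tfFromParams(best$fit$par, target), best$tf0)
  tf$t <- tf$t + (target - as.numeric(tf$R %*% pivot + tf$t))
  nt5 <- .applyTfRecord(nt5, tf)
  list(nt5 = nt5, nt3 = nt3, tf5 = tf)
}

#' Build a two-nucleotide Z-step fixture
#'
#' Two covalently plausible consecutive nucleotides: 5'-nt in anti with a
#' C2'-endo sugar, 3'-nt in syn, and the 5'-ribose O4' placed at a
#' configurable height over the 3'-base six-ring centroid (default 3.0
#' Angstrom on the 3'-face, i.e. an sO4'3 contact by construction).
#'
#' @param zOffset vertical O4' offset in Angstrom.
#' @param xyOffset in-plane offset from the six-ring centroid (length 2).
#' @param face face of the 3'-base the O4' is placed over (3 or 5).
#' @param base5,base3 base types of the 5'- and 3'-nucleotide.
#' @param chi3 glycosidic torsion of the 3'-nucleotide (syn by default).
#' @param sigma,seed optional Gaussian coordinate noise.
#' @return list with \code{records} (5'-nt, 3'-nt) and \code{expected}
#'   (the contact category and annotation string implied by the requested
#'   geometry; "none" when the geometry was built to fall outside the
#'   contact definition).
#' @examples
#' scanLpPi(asRNAStructure(buildZStep()$records))$category
#' @export
buildZStep <- function(zOffset = if (stacked) 3.4 else 3.0,
                       xyOffset = c(0, 0), face = 3L,
                       base5 = "C", base3 = "G", chi3 = 60,
                       stacked = FALSE, sigma = 0, seed = 1L) {
  cz <- .canonicalZStep(base5 = base5, base3 = base3, zOffset = zOffset,
                        xyOffset = xyOffset, face = face, chi3 = chi3,
                        stacked = stacked)
  records <- .snapBackbone(list(cz$nt5, cz$nt3))
  if (sigma > 0) records <- perturbRecords(records, sigma, seed)
  params <- lpPiParameters()
  category <- if (abs(zOffset) > params@zMin && abs(zOffset) <= params@zMaxTrue &&
                  .vnorm(xyOffset) < 0.5) "true"
  else if (abs(zOffset) > params@zMaxTrue && abs(zOffset) <= params@zMaxNear &&
           .vnorm(xyOffset) < 0.5) "near"
  else "none"
  expected <- list(category = category)
  if (category != "none")
    expected$oxygen_first <- .lppiStrings("O4'", face, category)[["oxygen_first"]]
  if (stacked) expected$stack <- "s53"
  list(records = records, expected = expected)
}

#' Build a Z_anti-step fixture
#'
#' Variant of the Z-step with the 3'-nucleobase in anti and the O4' contact
#' on its 5'-face (sO4'5).
#'
#' @inheritParams buildZStep
#' @return as \code{\link{buildZStep}}.
#' @export
buildZAntiStep <- function(zOffset = 3.0, sigma = 0, seed = 1L) {
  buildZStep(zOffset = zOffset, face = 5L, chi3 = -160, sigma = sigma,
             seed = seed)
}

# ---- base pairs ------------------------------------------------------------

# Heavy-atom hydrogen-bond target pairs (atom of nt1, atom of nt2) used to
# construct pairs; distances are driven to ~2.85 A.
.pairTargets <- list(
  cWW = list(GC = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
             CG = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
             AU = list(c("N6", "O4"), c("N1", "N3")),
             UA = list(c("O4", "N6"), c("N3", "N1"))),
  tSW = list(UG = list(c("O2", "N1"), c("O2'", "N2")),
             CG = list(c("O2", "N1"), c("O2'", "N2")),
             GA = list(c("N3", "N6"), c("N2", "N1"))))

# Place nt2 against a fixed nt1 so the target distances are met, the bases
# are coplanar and laterally arranged. trans pairing -> parallel normals.
.placePaired <- function(nt1, nt2, targets, orientation) {
  fr1 <- baseFrame(nt1)
  fr2 <- baseFrame(nt2)
  e1 <- colMeans(do.call(rbind, lapply(targets, function(p) .atomXYZ(nt1, p[1L]))))
  d <- .unit((e1 - fr1@center) - sum((e1 - fr1@center) * fr1@normal) * fr1@normal)
  nWant <- if (orientation == "trans") fr1@normal else -fr1@normal
  # initial orientation: align nt2's normal, then spin about it
  axis <- .cross(fr2@normal, nWant)
  R0 <- if (.vnorm(axis) < 1e-8) {
    if (sum(fr2@normal * nWant) > 0) diag(3) else .rotAxis(fr1@basis[, 1L], 180)
  } else .rotAxis(axis, .angle3(fr2@normal + fr2@center, fr2@center,
                                nWant + fr2@center))
  pivot <- fr2@center
  base2 <- setdiff(rownames(nt2$atoms), .sugarRing)
  obj <- function(tf) {
    at <- .tfApply(tf, nt2$atoms)
    dsum <- sum(vapply(targets, function(p)
      (.vnorm(.atomXYZ(nt1, p[1L]) - at[p[2L], ]) - 2.85)^2, numeric(1L)))
    pl2 <- .planeTLS(at[intersect(.baseHeavyAtoms[[nt2$base]], rownames(at)),
                        , drop = FALSE])
    cop <- acos(min(1, abs(sum(pl2$normal * fr1@normal))))^2
    lat <- max(0, abs(sum(.unit(pl2$center - fr1@center) * fr1@normal)) - 0.2)^2
    excl <- setdiff(rownames(at), vapply(targets, `[`, character(1L), 2L))
    clash <- .apartPenalty(at[excl, , drop = FALSE], nt1$atoms, 2.9)
    # cis/trans term from the sides the glycosidic bonds take (plane normal
    # signs cancel in the product, so the TLS normal suffices here)
    axis <- at["C1'", ] - .atomXYZ(nt1, "C1'")
    nm <- fr1@normal + sign(sum(fr1@normal * pl2$normal)) * pl2$normal
    g1 <- .atomXYZ(nt1, .glyN[[nt1$base]]) - .atomXYZ(nt1, "C1'")
    g2 <- at[.glyN[[nt2$base]], ] - at["C1'", ]
    a <- sum(nm * .cross(axis, g1)); b <- sum(nm * .cross(axis, g2))
    side <- (a * b) / max(1e-9, abs(a) * abs(b))
    wrongSide <- if (orientation == "trans") max(0, side) else max(0, -side)
    dsum + 3 * cop + 5 * lat + clash + 4 * wrongSide
  }
  inits <- lapply(c(0, 90, 180, 270), function(spin) {
    Ri <- .rotAxis(nWant, spin) %*% R0
    e2 <- .tfApply(list(R = Ri, t = as.numeric(pivot - Ri %*% pivot)),
                   do.call(rbind, lapply(targets, function(p)
                     matrix(.atomXYZ(nt2, p[2L]), 1L))))
    shift <- (e1 + 2.85 * d) - colMeans(e2)
    # express as the 6-parameter chart is impossible directly; optimise from
    # a transform seeded by this rotation/translation instead
    list(R = Ri, t = as.numeric(pivot - Ri %*% pivot) + shift)
  })
  best <- NULL
  for (tf0 in inits) {
    fit <- stats::optim(rep(0, 6), function(p) {
      tf <- .tfCompose(.tfFromParams(p, pivot), tf0)
      obj(tf)
    }, method = "Nelder-Mead",
    control = list(maxit = 4000, reltol = 1e-12,
                   parscale = c(30, 30, 30, 2, 2, 2)))
    if (is.null(best) || fit$value < best$fit$value)
      best <- list(fit = fit, tf0 = tf0)
  }
  tf <- .tfCompose(.tfFromParams(best$fit$par, pivot), best$tf0)
  list(nt2 = .applyTfRecord(nt2, tf), tf = tf, value = best$fit$value)
}

#' Build an isolated base-pair fixture
#'
#' Constructs two nucleotides engaged in a cWW or tSW pair with hydrogen-bond
#' heavy-atom distances near 2.85 Angstrom and coplanar bases. Supported
#' combinations: cWW GC/CG/AU/UA and tSW UG/CG/GA (the families needed by the
#' Z-turn queries).
#'
#' @param base1,base2 base types.
#' @param family "cWW" or "tSW".
#' @param nt1 optional pre-placed first nucleotide (used when threading pairs
#'   onto an existing scaffold).
#' @param chi1,chi2 glycosidic torsions of the two nucleotides.
#' @return list with \code{records} and the placement transform \code{tf}.
#' @examples
#' pr <- buildBasePair("G", "C", "cWW")
#' nrow(detectHBonds(pr$records[[1]], pr$records[[2]]))
#' @export
buildBasePair <- function(base1, base2, family = c("cWW", "tSW"),
                          nt1 = NULL, chi1 = -160, chi2 = -160) {
  family <- match.arg(family)
  combo <- paste0(base1, base2)
  targets <- .pairTargets[[family]][[combo]]
  if (is.null(targets))
    stop(sprintf("no construction recipe for %s %s", family, combo))
  if (is.null(nt1)) nt1 <- buildNucleotide(base1, chi = chi1, seq = 1L)
  nt2 <- buildNucleotide(base2, chi = chi2, seq = 2L, chain = nt1$chain)
  orientation <- if (substring(family, 1L, 1L) == "t") "trans" else "cis"
  pp <- .placePaired(nt1, nt2, targets, orientation)
  list(records = list(nt1, pp$nt2), tf = pp$tf, family = family)
}

# ---- continuity-only linker ------------------------------------------------

# Place `nt` (build frame) relative to fixed surroundings so its phosphate
# continues from `o3Prev` and (optionally) its O3' feeds `pNext`, staying
# `minDist` away from the `avoid` coordinates.
.placeLinker <- function(nt, o3Prev = NULL, pNext = NULL, avoid = NULL,
                         minDist = 4, guide = NULL) {
  pivot <- colMeans(nt$atoms)
  obj <- function(tf) {
    at <- .tfApply(tf, nt$atoms)
    v <- 0
    if (!is.null(o3Prev)) v <- v + (.vnorm(at["P", ] - o3Prev) - 1.6)^2
    if (!is.null(pNext)) v <- v + (.vnorm(pNext - at["O3'", ]) - 1.6)^2
    if (!is.null(avoid)) v <- v + .apartPenalty(at, avoid, minDist)
    if (!is.null(guide))
      v <- v + 0.05 * (.vnorm(colMeans(at) - guide) / 3)^2
    v
  }
  pl <- .placeRigid(obj, pivot)
  .applyTfRecord(nt, pl$tf)
}

# ---- UNCG Z-turn -----------------------------------------------------------

#' Build a six-nucleotide UNCG Z-turn fixture
#'
#' Stem nt + U-U-C-G tetraloop + stem nt with the planted structural
#' signature: a trans Sugar/Watson-Crick U2-G5 pair (hydrogen-bond distances
#' near 2.85 Angstrom), a CpG Z-step at positions 4-5 (sO4'3 contact) with
#' G5 in syn, and covalent continuity along all five steps.
#'
#' @param sigma,seed optional Gaussian coordinate noise.
#' @param breakPair displace G5 laterally by 5 Angstrom (backbone re-snapped)
#'   so that the closing pair and the contact are lost: the negative control.
#' @return list with \code{records} (6 nucleotides, chain A, numbers 1-6) and
#'   \code{expected} (planted pair family, contact string, hit count).
#' @examples
#' zt <- buildUNCGZTurn()
#' length(findZTurns(asRNAStructure(zt$records), template = "UNNG"))
#' @export
buildUNCGZTurn <- function(sigma = 0, seed = 1L, breakPair = FALSE) {
  cz <- .canonicalZStep(base5 = "C", base3 = "G")   # C4 (anti, C2'-endo), G5 (syn)
  g5 <- cz$nt3; g5$seq <- 5L
  c4 <- cz$nt5; c4$seq <- 4L
  pr <- .placePaired(g5, buildNucleotide("U", chi = -160, seq = 2L),
                     # targets seen from G5: G(N1)...U(O2), G(N2)...U(O2')
                     list(c("N1", "O2"), c("N2", "O2'")), "trans")
  u2 <- pr$nt2
  bases <- function(nts) do.call(rbind, lapply(nts, function(n)
    n$atoms[.baseHeavyAtoms[[n$base]], , drop = FALSE]))
  u3 <- .placeLinker(buildNucleotide("U", chi = -160, puckerP = 162, seq = 3L),
                     o3Prev = .atomXYZ(u2, "O3'"), pNext = .atomXYZ(c4, "P"),
                     avoid = bases(list(u2, c4, g5)), minDist = 3.5)
  c1 <- .placeLinker(buildNucleotide("C", chi = -160, seq = 1L),
                     pNext = .atomXYZ(u2, "P"),
                     avoid = rbind(bases(list(u2, u3, c4, g5)),
                                   .atomXYZ(g5, "O3'") + c(0, 0, 0)),
                     minDist = 4.5)
  g6 <- .placeLinker(buildNucleotide("G", chi = -160, seq = 6L),
                     o3Prev = .atomXYZ(g5, "O3'"),
                     avoid = rbind(bases(list(c1, u2, u3, c4, g5))),
                     minDist = 4.5)
  records <- list(c1, u2, u3, c4, g5, g6)
  if (breakPair) {
    fr5 <- baseFrame(g5)
    fr2 <- baseFrame(u2)
    shift <- 5 * .unit(fr5@center - fr2@center)
    records[[5L]]$atoms <- sweep(records[[5L]]$atoms, 2L, shift, "+")
  }
  records <- .snapBackbone(records)
  if (sigma > 0) records <- perturbRecords(records, sigma, seed)
  list(records = records,
       expected = list(pair = if (breakPair) NA_character_ else "tSW",
                       contact = if (breakPair) NA_character_ else "sO4′3",
                       hits = if (breakPair) 0L else 1L))
}

# ---- A-form duplex ---------------------------------------------------------

.complement <- c(A = "U", U = "A", G = "C", C = "G")

# Helical screw transform: rotation `twist` degrees about z plus rise along z.
.tfHelical <- function(i, twist = 32.7, rise = 2.81) {
  list(R = .rotAxis(c(0, 0, 1), i * twist), t = c(0, 0, i * rise))
}

# Reference placement of a built nucleotide into the helix frame. The
# 3'-face normal is placed along +z (the ascent direction of the strand);
# consistently, the O3' atom — the 3'-linkage — then sits on the
# positive-normal side of the base, which corroborates the stored sign
# convention independently of the phosphate-arm torsions (methods vignette).
.aformReference <- function(nt, twist = 32.7, rise = 2.81) {
  fr <- baseFrame(nt)
  place <- function(sgn) {
    nWant <- c(0, 0, sgn)
    axis <- .cross(fr@normal, nWant)
    R0 <- if (.vnorm(axis) < 1e-8) diag(3) else
      .rotAxis(axis, .angle3(fr@normal + fr@center, fr@center, nWant + fr@center))
    tf0 <- list(R = R0, t = as.numeric(-R0 %*% fr@center))
    # base plane stays exactly perpendicular to the axis: only the spin about
    # z and the in-plane offset are optimised
    mk <- function(p) {
      Rz <- .rotAxis(c(0, 0, 1), p[1L])
      list(R = Rz %*% tf0$R,
           t = as.numeric(Rz %*% tf0$t) + c(p[2L], p[3L], 0))
    }
    obj <- function(p) {
      at <- .tfApply(mk(p), nt$atoms)
      nxt <- .tfApply(.tfHelical(1, twist, rise), at)
      gap <- (.vnorm(nxt["P", ] - at["O3'", ]) - 1.6)^2
      radial <- (.vnorm(colMeans(at[.baseHeavyAtoms[[nt$base]], ])[1:2]) - 2)^2
      gap + 0.2 * radial
    }
    best <- NULL
    for (spin0 in seq(0, 300, by = 60)) {
      fit <- stats::optim(c(spin0, 0, 0), obj, method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-12,
                                         parscale = c(30, 2, 2)))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    list(tf = mk(best$par), value = best$value, sgn = sgn)
  }
  place(1)
}

#' Build an A-form-like duplex fixture
#'
#' A right-handed double helix (twist 32.7 degrees, rise 2.81 Angstrom per
#' step) of anti, C3'-endo nucleotides, with every step of strand A paired
#' cWW to the complementary strand B. Used as the regular-helix negative
#' control (no Z-steps, no tSW pairs, head-to-tail riboses) and as the
#' calibration scaffold for the 3'-face normal convention.
#'
#' @param sequence strand-A sequence 5'->3' (characters among A, C, G, U).
#' @param duplex build the complementary strand too.
#' @return list with \code{records} (strand A then strand B, B numbered in
#'   its own 5'->3' order).
#' @export
buildAFormDuplex <- function(sequence = "GACGUC", duplex = TRUE) {
  bases <- strsplit(sequence, "")[[1L]]
  stopifnot(all(bases %in% .rnaBases))
  builds <- lapply(.rnaBases, function(b) buildNucleotide(b, chi = -158, puckerP = 18))
  names(builds) <- .rnaBases
  ref <- .aformReference(builds[[bases[1L]]])
  strandA <- lapply(seq_along(bases), function(i) {
    nt <- builds[[bases[i]]]
    nt$seq <- i; nt$chain <- "A"
    .applyTfRecord(nt, .tfCompose(.tfHelical(i - 1L), ref$tf))
  })
  records <- .snapBackbone(strandA)
  if (duplex) {
    # pairing transform per base type, computed once against the helix-index-0
    # placement and propagated by the screw symmetry
    pairTf <- lapply(unique(bases), function(b) {
      bp <- buildBasePair(b, .complement[[b]], "cWW",
                          nt1 = .applyTfRecord(builds[[b]], ref$tf))
      bp$tf
    })
    names(pairTf) <- unique(bases)
    n <- length(bases)
    strandB <- lapply(seq_along(bases), function(i) {
      nt <- builds[[.complement[[bases[i]]]]]
      nt$seq <- n - i + 1L; nt$chain <- "B"
      .applyTfRecord(nt, .tfCompose(.tfHelical(i - 1L), pairTf[[bases[i]]]))
    })
    strandB <- strandB[order(vapply(strandB, function(x) x$seq, integer(1L)))]
    strandB <- .snapBackbone(strandB)
    records <- c(records, strandB)
  }
  list(records = records)
}

# ---- Z-helix ---------------------------------------------------------------

#' Build a single-strand Z-helix-like fixture
#'
#' An alternating C-G strand in which every CpG step is a planted Z-step
#' (sO4'3 contact, 3'-G syn) and every GpC step is a continuity-only linker,
#' mimicking the alternation of a Z-form helix strand.
#'
#' @param nSteps number of CpG Z-steps (sequence length = 2 * nSteps).
#' @return list with \code{records} and \code{expected} (planted Z-step
#'   count and step sequence).
#' @examples
#' zh <- buildZHelix(3)
#' sum(scanLpPi(asRNAStructure(zh$records))$category == "true")
#' @export
buildZHelix <- function(nSteps = 3L) {
  cz <- .canonicalZStep()
  tfCG <- .tfInverse(cz$tf5)        # transform of G relative to a placed C
  cBuild <- buildNucleotide("C", chi = -160, puckerP = 162)
  gBuild <- buildNucleotide("G", chi = 60, puckerP = 18)
  # continuity-only GpC arrangement, computed once in the G build frame
  linked <- .placeLinker(cBuild, o3Prev = .atomXYZ(gBuild, "O3'"),
                         avoid = gBuild$atoms, minDist = 4.5,
                         guide = colMeans(gBuild$atoms) +
                           6 * .unit(.atomXYZ(gBuild, "O3'") - colMeans(gBuild$atoms)))
  # transform that carried cBuild to its continuity-linked placement
  tfGC <- .recoverTf(cBuild$atoms, linked$atoms)
  records <- list()
  M <- .tfIdentity()
  for (k in seq_len(nSteps)) {
    cnt <- cBuild; cnt$seq <- 2L * k - 1L
    records[[length(records) + 1L]] <- .applyTfRecord(cnt, M)
    Mg <- .tfCompose(M, tfCG)
    gnt <- gBuild; gnt$seq <- 2L * k
    records[[length(records) + 1L]] <- .applyTfRecord(gnt, Mg)
    M <- .tfCompose(Mg, tfGC)
  }
  records <- .snapBackbone(records)
  list(records = records,
       expected = list(nZSteps = nSteps, sequence = "CpG"))
}

# Exact rigid transform mapping coordinate set A onto B (same atoms).
.recoverTf <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  s <- svd(t(sweep(A, 2L, ca)) %*% sweep(B, 2L, cb))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

# ---- file output -----------------------------------------------------------

#' Write records to a minimal PDB or mmCIF file
#'
#' PDB output goes through \code{bio3d::write.pdb}; mmCIF output is a minimal
#' \code{atom_site} loop (no R package writes mmCIF). Round-tripping fixtures
#' through \code{\link{readStructure}} is part of the test surface.
#'
#' @param x an \code{RNAStructure} or list of records.
#' @param path output file.
#' @param format "pdb" or "mmcif".
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  nts <- if (is(x, "RNAStructure")) nucleotides(x) else x
  sid <- if (is(x, "RNAStructure")) x@structureId else "FIXT"
  rows <- do.call(rbind, lapply(nts, function(nt) {
    data.frame(elety = rownames(nt$atoms), resid = nt$base, chain = nt$chain,
               resno = nt$seq, insert = ifelse(nzchar(nt$icode), nt$icode, ""),
               x = nt$atoms[, 1L], y = nt$atoms[, 2L], z = nt$atoms[, 3L],
               o = nt$occ[rownames(nt$atoms)],
               alt = nt$altloc[rownames(nt$atoms)],
               model = nt$model, stringsAsFactors = FALSE)
  }))
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(rows)), resno = rows$resno,
                     resid = rows$resid, chain = rows$chain,
                     insert = rows$insert, elety = rows$elety, o = rows$o,
                     b = rep(0, nrow(rows)),
                     elesy = substr(rows$elety, 1L, 1L))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("data_%s", sid), con)
    writeLines(c("#", "loop_", "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.label_atom_id",
                 "_atom_site.label_alt_id", "_atom_site.label_comp_id",
                 "_atom_site.label_asym_id", "_atom_site.label_entity_id",
                 "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
                 "_atom_site.Cartn_x", "_atom_site.Cartn_y",
                 "_atom_site.Cartn_z", "_atom_site.occupancy",
                 "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
                 "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
                 "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"),
               con)
    alt <- ifelse(nzchar(rows$alt), rows$alt, ".")
    ins <- ifelse(nzchar(rows$insert), rows$insert, "?")
    writeLines(sprintf(
      "ATOM %d %s \"%s\" %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s \"%s\" %d",
      seq_len(nrow(rows)), substr(rows$elety, 1L, 1L), rows$elety, alt,
      rows$resid, rows$chain, rows$resno, ins, rows$x, rows$y, rows$z,
      rows$o, rows$resno, rows$resid, rows$chain, rows$elety, rows$model),
      con)
    writeLines("#", con)
  }
  invisible(path)
}
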