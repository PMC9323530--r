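# Hydrogen-bond detection, a reduced Leontis-Westhof base-pair classifier
# (the families the Z-turn queries need: cWW, tSW/tWS and their "near"
# forms; other families are reported with a provisional marker) and
# face-face stacking classification (s33/s35/s53/s55).

# Donor atoms with their covalent antecedents (angle reference atoms).
.hbDonors <- list(
  A = list(N6 = "C6"),
  G = list(N1 = c("C2", "C6"), N2 = "C2"),
  C = list(N4 = "C4"),
  U = list(N3 = c("C2", "C4"))
)
.hbAcceptors <- list(
  A = c("N1", "N3", "N7"),
  G = c("O6", "N3", "N7"),
  C = c("O2", "N3"),
  U = c("O2", "O4")
)
.sugarDonors <- list(`O2'` = "C2'")
.sugarAcceptors <- c("O2'", "O4'")

# Leontis-Westhof edge membership (atoms may sit on two edges, e.g. the
# pyrimidine O2 on both the Watson-Crick and the sugar edge); the 2'-OH
# counts as sugar edge.
.lwEdges <- list(
  A = list(W = c("N1", "N6"), H = c("N6", "N7"), S = c("N3", "O2'")),
  G = list(W = c("N1", "N2", "O6"), H = c("N7", "O6"),
           S = c("N3", "N2", "O2'")),
  C = list(W = c("N3", "N4", "O2"), H = "N4", S = c("O2", "O2'")),
  U = list(W = c("N3", "O4", "O2"), H = "O4", S = c("O2", "O2'"))
)

.donorsOf <- function(nt) c(.hbDonors[[nt$base]], .sugarDonors)
.acceptorsOf <- function(nt) c(.hbAcceptors[[nt$base]], .sugarAcceptors)

#' Detect hydrogen bonds between two nucleotides
#'
#' Geometric criteria on heavy atoms: donor-acceptor distance <=
#' \code{distMax} (or <= \code{nearDistMax} for "near" bonds) and
#' donor-antecedent/donor-acceptor angle >= \code{angleMin} degrees. Donor
#' and acceptor sets cover the base edges plus the 2'-hydroxyl and O4'.
#'
#' @param nt1,nt2 nucleotide records.
#' @param distMax,nearDistMax,angleMin criteria.
#' @return data.frame with donor side (1 or 2), donor atom, acceptor atom,
#'   distance, angle and a near flag; zero rows when none.
#' @export
detectHBonds <- function(nt1, nt2, distMax = 3.5, nearDistMax = 4.0,
                         angleMin = 110) {
  out <- list()
  scan <- function(don, acc, side) {
    donors <- .donorsOf(don)
    accs <- intersect(.acceptorsOf(acc), rownames(acc$atoms))
    for (dAtom in intersect(names(donors), rownames(don$atoms))) {
      dxyz <- .atomXYZ(don, dAtom)
      ants <- intersect(donors[[dAtom]], rownames(don$atoms))
      if (!length(ants)) next
      for (aAtom in accs) {
        axyz <- .atomXYZ(acc, aAtom)
        dd <- .vnorm(dxyz - axyz)
        if (dd > nearDistMax || dd < 1e-6) next
        ang <- max(vapply(ants, function(an)
          .angle3(.atomXYZ(don, an), dxyz, axyz), numeric(1L)))
        if (ang < angleMin) next
        out[[length(out) + 1L]] <<- data.frame(
          donor_side = side, donor = dAtom, acceptor = aAtom,
          distance = dd, angle = ang, near = dd > distMax,
          stringsAsFactors = FALSE)
      }
    }
  }
  scan(nt1, nt2, 1L)
  scan(nt2, nt1, 2L)
  if (!length(out))
    return(data.frame(donor_side = integer(), donor = character(),
                      acceptor = character(), distance = numeric(),
                      angle = numeric(), near = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Normalised product of the signed sides the two glycosidic bonds take
# relative to the C1'-C1' axis in the mean pair plane: positive = same side
# (cis), negative = opposite sides (trans).
.glycosidicSides <- function(nt1, nt2, fr1 = NULL, fr2 = NULL) {
  if (is.null(fr1)) fr1 <- baseFrame(nt1)
  if (is.null(fr2)) fr2 <- baseFrame(nt2)
  axis <- .atomXYZ(nt2, "C1'") - .atomXYZ(nt1, "C1'")
  nm <- .unit(fr1@normal + sign(sum(fr1@normal * fr2@normal)) * fr2@normal)
  g1 <- .atomXYZ(nt1, .glyN[[nt1$base]]) - .atomXYZ(nt1, "C1'")
  g2 <- .atomXYZ(nt2, .glyN[[nt2$base]]) - .atomXYZ(nt2, "C1'")
  a <- sum(nm * .cross(axis, g1))
  b <- sum(nm * .cross(axis, g2))
  (a * b) / max(1e-9, abs(a) * abs(b))
}

# Majority-vote edge assignment from the hydrogen-bonded atoms of one base;
# votes are weighted by bond strength (4.1 - distance) so that shared atoms
# (e.g. the pyrimidine O2) cannot force ties.
.edgeVote <- function(base, atoms, weights) {
  votes <- c(W = 0, H = 0, S = 0)
  for (k in seq_along(atoms))
    for (e in names(.lwEdges[[base]]))
      if (atoms[k] %in% .lwEdges[[base]][[e]])
        votes[e] <- votes[e] + weights[k]
  if (all(votes == 0)) return(NA_character_)
  top <- names(votes)[abs(votes - max(votes)) < 1e-9]
  if (length(top) > 1L) return(NA_character_)
  top
}

#' Classify the Leontis-Westhof family of a nucleotide pair
#'
#' Edges are assigned per base by majority vote over the hydrogen-bonded
#' atoms' edge membership; cis/trans comes from the side of the C1'-C1' axis
#' each glycosidic bond falls on in the mean pair plane. A true pair needs at
#' least one strict hydrogen bond, inter-plane angle <= \code{coplanarMax}
#' and a lateral (non-stacked) arrangement; "near" pairs satisfy only the
#' near hydrogen-bond criteria or have borderline coplanarity (35-55
#' degrees). Families other than cWW and tSW/tWS are reported with
#' \code{provisional = TRUE}.
#'
#' @param nt1,nt2 nucleotide records.
#' @param coplanarMax,coplanarNearMax coplanarity limits (degrees).
#' @param lateralMax maximum |cosine| between the inter-center line and each
#'   base normal.
#' @return one-row data.frame (family, edges, orientation, near, provisional,
#'   hydrogen-bond count, coplanarity) with the bond table attached as
#'   attribute \code{"hbonds"}, or NULL when the two bases do not pair.
#' @examples
#' pr <- buildBasePair("G", "C", "cWW")
#' classifyBasePair(pr$records[[1]], pr$records[[2]])$family
#' @export
classifyBasePair <- function(nt1, nt2, coplanarMax = 35,
                             coplanarNearMax = 55, lateralMax = 0.5) {
  fr1 <- suppressWarnings(baseFrame(nt1))
  fr2 <- suppressWarnings(baseFrame(nt2))
  if (is.null(fr1) || is.null(fr2)) return(NULL)
  hb <- detectHBonds(nt1, nt2)
  if (!nrow(hb)) return(NULL)
  strict <- hb[!hb$near, , drop = FALSE]
  use <- if (nrow(strict)) strict else hb
  u <- .unit(fr2@center - fr1@center)
  if (abs(sum(u * fr1@normal)) > lateralMax ||
      abs(sum(u * fr2@normal)) > lateralMax) return(NULL)
  cop <- acos(min(1, abs(sum(fr1@normal * fr2@normal)))) * 180 / pi
  if (cop > coplanarNearMax) return(NULL)
  near <- (nrow(strict) == 0L) || cop > coplanarMax
  w <- pmax(0.1, 4.1 - use$distance)
  atoms1 <- ifelse(use$donor_side == 1L, use$donor, use$acceptor)
  atoms2 <- ifelse(use$donor_side == 2L, use$donor, use$acceptor)
  e1 <- .edgeVote(nt1$base, atoms1, w)
  e2 <- .edgeVote(nt2$base, atoms2, w)
  if (is.na(e1) || is.na(e2)) {
    message(sprintf("pair %s-%s: ambiguous edge assignment, not classified",
                    ntKey(nt1), ntKey(nt2)))
    return(NULL)
  }
  orientation <- if (.glycosidicSides(nt1, nt2, fr1, fr2) > 0) "cis" else "trans"
  family <- paste0(substring(orientation, 1L, 1L), e1, e2)
  data.frame(nt1 = ntKey(nt1), nt2 = ntKey(nt2), base1 = nt1$base,
             base2 = nt2$base, family = family, edge1 = e1, edge2 = e2,
             orientation = orientation, near = near,
             provisional = !(family %in% c("cWW", "tSW", "tWS")),
             n_hbonds = nrow(use), coplanarity = cop,
             stringsAsFactors = FALSE) -> res
  attr(res, "hbonds") <- hb
  res
}

#' Classify base-base stacking faces
#'
#' A stack is annotated when each base's center projects within the other's
#' expanded-ellipse system with 2.0 < |z| <= \code{zMax} Angstrom; "near"
#' when exactly one direction passes the strict test. The face code reads
#' nt1-face then nt2-face: s53 means nt1's 5'-face meets nt2's 3'-face.
#'
#' @param nt1,nt2 nucleotide records.
#' @param zMin,zMax vertical band (Angstrom).
#' @return one-row data.frame (faces, near, z_offset) or NULL.
#' @export
classifyStacking <- function(nt1, nt2, zMin = 2.0, zMax = 4.5) {
  fr1 <- suppressWarnings(baseFrame(nt1))
  fr2 <- suppressWarnings(baseFrame(nt2))
  if (is.null(fr1) || is.null(fr2)) return(NULL)
  p12 <- projectOntoFrame(fr1, fr2@center)   # nt2 center in nt1 frame
  p21 <- projectOntoFrame(fr2, fr1@center)
  ok <- function(p, fr) {
    abs(p[["z"]]) > zMin && abs(p[["z"]]) <= zMax &&
      locateProjection(fr, p[c("x", "y")])$status != "outside"
  }
  ok12 <- ok(p12, fr1)
  ok21 <- ok(p21, fr2)
  if (!ok12 && !ok21) return(NULL)
  near <- xor(ok12, ok21)
  f1 <- if (p12[["z"]] > 0) 3L else 5L   # which face of nt1 meets nt2
  f2 <- if (p21[["z"]] > 0) 3L else 5L
  data.frame(nt1 = ntKey(nt1), nt2 = ntKey(nt2),
             faces = sprintf("s%d%d", f1, f2), near = near,
             z_offset = mean(c(abs(p12[["z"]]), abs(p21[["z"]]))),
             stringsAsFactors = FALSE)
}

#' Pair table of a structure
#'
#' Classifies every nucleotide pair whose C1' atoms lie within
#' \code{maxC1C1} Angstrom; each unordered pair is reported once, in
#' (model, chain, number) order.
#'
#' @param x an \code{RNAStructure}.
#' @param maxC1C1 candidate pruning distance (Angstrom).
#' @return data.frame of pair annotations (possibly empty).
#' @export
annotatePairs <- function(x, maxC1C1 = 12) {
  nts <- nucleotides(x)
  ord <- order(vapply(nts, function(n) n$model, integer(1L)),
               vapply(nts, function(n) n$chain, character(1L)),
               vapply(nts, function(n) n$seq, integer(1L)))
  nts <- nts[ord]
  out <- list()
  c1 <- lapply(nts, .atomXYZ, "C1'")
  for (i in seq_along(nts)) {
    if (is.null(c1[[i]])) next
    for (j in seq_along(nts)) {
      if (j <= i) next
      if (nts[[j]]$model != nts[[i]]$model) next
      if (is.null(c1[[j]]) || .vnorm(c1[[i]] - c1[[j]]) > maxC1C1) next
      p <- classifyBasePair(nts[[i]], nts[[j]])
      if (!is.null(p)) {
        p$structure_id <- x@structureId
        out[[length(out) + 1L]] <- p
      }
    }
  }
  if (!length(out))
    return(data.frame(nt1 = character(), nt2 = character(),
                      base1 = character(), base2 = character(),
                      family = character(), edge1 = character(),
                      edge2 = character(), orientation = character(),
                      near = logical(), provisional = logical(),
                      n_hbonds = integer(), coplanarity = numeric(),
                      structure_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
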