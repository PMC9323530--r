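# Glycosidic conformation, sugar pucker (pseudorotation) and the ribose
# head-to-head orientation heuristic.

.SIN36 <- sin(36 * pi / 180)
.SIN72 <- sin(72 * pi / 180)

# The five endocyclic torsions nu0..nu4 of a ribose, in the conventional
# order (nu2 = C1'-C2'-C3'-C4').
.sugarTorsions <- function(nt) {
  g <- function(n) .atomXYZ(nt, n)
  c(nu0 = .torsion(g("C4'"), g("O4'"), g("C1'"), g("C2'")),
    nu1 = .torsion(g("O4'"), g("C1'"), g("C2'"), g("C3'")),
    nu2 = .torsion(g("C1'"), g("C2'"), g("C3'"), g("C4'")),
    nu3 = .torsion(g("C2'"), g("C3'"), g("C4'"), g("O4'")),
    nu4 = .torsion(g("C3'"), g("C4'"), g("O4'"), g("C1'")))
}

#' Glycosidic torsion and syn/anti class
#'
#' chi is the torsion O4'-C1'-N9-C4 (purines) or O4'-C1'-N1-C2 (pyrimidines).
#' The default windows are syn for chi in [0, 90] degrees and anti for chi in
#' [150, 180] or (-180, -90]; everything else is "intermediate". The windows
#' are arguments because chi values of Z-step 3'-nucleotides are often
#' borderline and motif queries may prefer stacking-face constraints instead.
#'
#' @param nt a nucleotide record.
#' @param synWindow,antiWindow class windows in degrees; \code{antiWindow}
#'   wraps through 180.
#' @return list(chi, cls) or NULL (with a warning) when an atom is missing.
#' @examples
#' annotateGlycosidic(buildNucleotide("G", chi = 60, puckerP = 162))$cls
#' @export
annotateGlycosidic <- function(nt, synWindow = c(0, 90),
                               antiWindow = c(150, -90)) {
  need <- c("O4'", "C1'", .glyN[[nt$base]], .chiBaseAtom[[nt$base]])
  if (!.hasAtoms(nt, need)) {
    warning(sprintf("nucleotide %s: missing chi atom", ntKey(nt)))
    return(NULL)
  }
  chi <- .torsion(.atomXYZ(nt, need[1L]), .atomXYZ(nt, need[2L]),
                  .atomXYZ(nt, need[3L]), .atomXYZ(nt, need[4L]))
  cls <- "intermediate"
  if (chi >= synWindow[1L] && chi <= synWindow[2L]) cls <- "syn"
  else if (chi >= antiWindow[1L] || chi <= antiWindow[2L]) cls <- "anti"
  list(chi = chi, cls = cls)
}

#' Sugar pucker by pseudorotation
#'
#' Phase P and amplitude from the standard arctangent combination of the five
#' endocyclic torsions. Class bands: C3'-endo for P in [0, 36), C4'-exo for
#' [36, 72), C2'-endo for [144, 180), otherwise "other". A flat ring
#' (amplitude below \code{degenerateAmplitude}) is flagged degenerate and
#' classed "other".
#'
#' @param nt a nucleotide record with the five ribose ring atoms.
#' @param degenerateAmplitude amplitude (degrees) below which the phase is
#'   meaningless.
#' @return list(phaseP, amplitude, cls, degenerate) or NULL with a warning.
#' @examples
#' annotateSugarPucker(buildNucleotide("C", chi = -160, puckerP = 162))$cls
#' @export
annotateSugarPucker <- function(nt, degenerateAmplitude = 1) {
  if (!.hasAtoms(nt, .sugarRing)) {
    warning(sprintf("nucleotide %s: missing ribose ring atom", ntKey(nt)))
    return(NULL)
  }
  nu <- .sugarTorsions(nt)
  num <- (nu["nu4"] + nu["nu1"]) - (nu["nu3"] + nu["nu0"])
  den <- 2 * nu["nu2"] * (.SIN36 + .SIN72)
  if (abs(num) < 1e-9 && abs(den) < 1e-9) {
    return(list(phaseP = 0, amplitude = 0, cls = "other", degenerate = TRUE))
  }
  P <- as.numeric(atan2(num, den)) * 180 / pi
  if (P < 0) P <- P + 360
  amp <- nu[["nu2"]] / cos(P * pi / 180)
  degen <- abs(amp) < degenerateAmplitude
  cls <- if (degen) "other"
  else if (P >= 0 && P < 36) "C3'-endo"
  else if (P >= 36 && P < 72) "C4'-exo"
  else if (P >= 144 && P < 180) "C2'-endo"
  else "other"
  list(phaseP = as.numeric(P), amplitude = as.numeric(amp), cls = cls,
       degenerate = degen)
}

#' Mutual ribose orientation of two nucleotides
#'
#' Advisory head-to-head / head-to-tail call: head-to-head (the Z-step
#' arrangement) when the O4'->C1' direction vectors of the two riboses point
#' against each other and each O4' lies on the side of the other ribose's
#' mean plane that faces it; head-to-tail (the regular-helix arrangement)
#' when the direction vectors agree. Never used as a hard filter by the
#' canned queries.
#'
#' @param nt1,nt2 nucleotide records with complete riboses.
#' @return "head_to_head", "head_to_tail" or "undetermined".
#' @export
riboseOrientation <- function(nt1, nt2) {
  if (!.hasAtoms(nt1, .sugarRing) || !.hasAtoms(nt2, .sugarRing))
    return("undetermined")
  u1 <- .unit(.atomXYZ(nt1, "C1'") - .atomXYZ(nt1, "O4'"))
  u2 <- .unit(.atomXYZ(nt2, "C1'") - .atomXYZ(nt2, "O4'"))
  dp <- sum(u1 * u2)
  if (dp > 0) return("head_to_tail")
  facing <- function(a, b) {
    ringA <- a$atoms[.sugarRing, , drop = FALSE]
    pl <- .planeTLS(ringA)
    n <- pl$normal
    cb <- colMeans(b$atoms[.sugarRing, , drop = FALSE])
    if (sum(n * (cb - pl$center)) < 0) n <- -n
    sum(n * (.atomXYZ(b, "O4'") - pl$center)) > 0
  }
  if (facing(nt1, nt2) && facing(nt2, nt1)) "head_to_head" else "undetermined"
}

#' Per-nucleotide conformation table
#'
#' @param x an \code{RNAStructure}.
#' @return data.frame with key, base, chi, chi class, pseudorotation phase,
#'   amplitude and pucker class for every annotatable nucleotide.
#' @export
annotateConformation <- function(x) {
  nts <- nucleotides(x)
  rows <- lapply(nts, function(nt) {
    g <- suppressWarnings(annotateGlycosidic(nt))
    p <- suppressWarnings(annotateSugarPucker(nt))
    data.frame(structure_id = x@structureId, nt = ntKey(nt), base = nt$base,
               chi = if (is.null(g)) NA_real_ else g$chi,
               chi_class = if (is.null(g)) NA_character_ else g$cls,
               pucker_P = if (is.null(p)) NA_real_ else p$phaseP,
               pucker_amplitude = if (is.null(p)) NA_real_ else p$amplitude,
               pucker_class = if (is.null(p)) NA_character_ else p$cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
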