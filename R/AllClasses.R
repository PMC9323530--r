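#' @import methods
NULL

#' Parameters of the lone-pair...pi contact annotator
#'
#' Holds the geometric cutoffs of the oxygen...pi contact definition: the
#' vertical band of a true contact (\code{zMin} < |z| <= \code{zMaxTrue}),
#' the extended band of a "near" contact in the vertical direction
#' (\code{zMaxTrue} < |z| <= \code{zMaxNear}), the radial expansion of the
#' per-ring ellipse used for lateral "near" contacts, and the set of backbone
#' oxygen atoms considered as donors. Nucleobase oxygens (O2, O4, O6) and
#' nitrogens are never donors.
#'
#' @slot zMin lower |z| bound (Angstrom) excluding in-plane contacts.
#' @slot zMaxTrue upper |z| bound (Angstrom) of a true contact.
#' @slot zMaxNear upper |z| bound (Angstrom) of a vertical near contact.
#' @slot ellipseExpansion radial expansion (Angstrom) of the fitted ring
#'   ellipse defining the lateral near zone.
#' @slot oxygenAtoms character vector of donor atom names.
#' @slot nearLowerBound logical; apply \code{zMin} also to lateral near
#'   contacts (the in-plane exclusion is part of the contact definition; the
#'   toggle exists for sensitivity analysis).
#' @slot includeIntra logical; include a nucleotide's own backbone oxygens
#'   over its own base (diagnostics only).
#' @exportClass LpPiParameters
setClass("LpPiParameters", representation(
  zMin = "numeric", zMaxTrue = "numeric", zMaxNear = "numeric",
  ellipseExpansion = "numeric", oxygenAtoms = "character",
  nearLowerBound = "logical", includeIntra = "logical"
))

setValidity("LpPiParameters", function(object) {
  msg <- character()
  if (!(object@zMin >= 0)) msg <- c(msg, "zMin must be >= 0")
  if (!(object@zMin < object@zMaxTrue)) msg <- c(msg, "zMin must be < zMaxTrue")
  if (!(object@zMaxTrue < object@zMaxNear))
    msg <- c(msg, "zMaxTrue must be < zMaxNear")
  if (object@ellipseExpansion < 0) msg <- c(msg, "ellipseExpansion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct lone-pair...pi annotation parameters
#'
#' Defaults encode the published contact definition: 2.0 Angstrom in-plane
#' exclusion, 3.5 Angstrom true band, 3.6 Angstrom vertical near band and a
#' 0.3 Angstrom ellipse expansion for lateral near contacts.
#'
#' @param zMin,zMaxTrue,zMaxNear,ellipseExpansion numeric cutoffs (Angstrom).
#' @param oxygenAtoms backbone oxygen atom names considered as donors
#'   (Unicode prime or ASCII apostrophe accepted).
#' @param nearLowerBound apply \code{zMin} to lateral near contacts too.
#' @param includeIntra include intra-nucleotide contacts (diagnostics).
#' @return an \code{LpPiParameters} object.
#' @examples
#' lpPiParameters()
#' lpPiParameters(zMaxTrue = 4.0, zMaxNear = 4.1)
#' @export
lpPiParameters <- function(zMin = 2.0, zMaxTrue = 3.5, zMaxNear = 3.6,
                           ellipseExpansion = 0.3,
                           oxygenAtoms = c("OP1", "OP2", "O2'", "O3'", "O4'", "O5'"),
                           nearLowerBound = TRUE, includeIntra = FALSE) {
  new("LpPiParameters", zMin = zMin, zMaxTrue = zMaxTrue, zMaxNear = zMaxNear,
      ellipseExpansion = ellipseExpansion,
      oxygenAtoms = .asciiName(oxygenAtoms),
      nearLowerBound = nearLowerBound, includeIntra = includeIntra)
}

setMethod("show", "LpPiParameters", function(object) {
  cat("LpPiParameters:",
      sprintf("%.2f < |z| <= %.2f A (true), |z| <= %.2f A (near),",
              object@zMin, object@zMaxTrue, object@zMaxNear),
      sprintf("ellipse +%.2f A", object@ellipseExpansion), "\n")
  cat("  donors:", paste(.displayName(object@oxygenAtoms), collapse = ", "), "\n")
})

#' Fitted ellipse of a nucleobase ring
#'
#' Least-squares ellipse through the in-plane positions of the five or six
#' ring atoms, together with the radial expansion factor that places the
#' expanded boundary a fixed distance beyond the most outlying ring atom.
#'
#' @slot ringAtoms atom names of the ring, in cyclic order.
#' @slot center2d ellipse center in in-plane coordinates.
#' @slot semiAxes (a, b), a >= b, in Angstrom.
#' @slot orientation major-axis angle, radians.
#' @slot expansion radial expansion in Angstrom (0 = fitted ellipse).
#' @slot residual RMS point-to-boundary distance of the fit.
#' @slot poly in-plane ring-atom polygon (vertices in cyclic order).
#' @exportClass RingEllipse
setClass("RingEllipse", representation(
  ringAtoms = "character", center2d = "numeric", semiAxes = "numeric",
  orientation = "numeric", expansion = "numeric", residual = "numeric",
  poly = "matrix"
))

setValidity("RingEllipse", function(object) {
  if (length(object@semiAxes) != 2L) return("semiAxes must have length 2")
  if (!(object@semiAxes[1L] >= object@semiAxes[2L] && object@semiAxes[2L] > 0))
    return("semi-axes must satisfy a >= b > 0")
  TRUE
})

#' Nucleobase reference frame
#'
#' Geometric center of the base heavy atoms, the signed unit normal (positive
#' side = 3'-face), an orthonormal in-plane basis, and the fitted ring
#' ellipse(s) (one for pyrimidines, two for purines; ring 1 is always the
#' six-membered ring).
#'
#' @slot base base type (A, C, G or U).
#' @slot center 3-D geometric center (Angstrom).
#' @slot normal unit normal pointing toward the 3'-face.
#' @slot basis 3 x 2 matrix of orthonormal in-plane vectors.
#' @slot rings list of \code{RingEllipse} objects.
#' @exportClass BaseFrame
setClass("BaseFrame", representation(
  base = "character", center = "numeric", normal = "numeric",
  basis = "matrix", rings = "list"
))

setValidity("BaseFrame", function(object) {
  msg <- character()
  if (abs(.vnorm(object@normal) - 1) > 1e-8) msg <- c(msg, "|normal| must be 1")
  if (any(abs(crossprod(object@basis, object@normal)) > 1e-8))
    msg <- c(msg, "normal must be orthogonal to the in-plane basis")
  if (length(object@rings) < 1L) msg <- c(msg, "at least one ring required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BaseFrame", function(object) {
  cat(sprintf("BaseFrame (%s): center (%.2f, %.2f, %.2f), %d ring(s)\n",
              object@base, object@center[1L], object@center[2L],
              object@center[3L], length(object@rings)))
})

#' An RNA-containing structure with per-nucleotide records
#'
#' Container produced by \code{\link{readStructure}} or by the fixture
#' builders: structure-level metadata plus one record per RNA residue per
#' model. Each record is a list with the residue identity (model, chain,
#' author sequence number, insertion code, base type) and named atom
#' coordinates, occupancies and altloc identifiers.
#'
#' @slot structureId structure identifier (PDB id or fixture name).
#' @slot resolution resolution in Angstrom, or NA when not stated.
#' @slot method experimental method string (may be empty).
#' @slot nModels number of models in the source file.
#' @slot nucleotides list of nucleotide records.
#' @slot skipped named integer vector of skipped residue counts (modified
#'   nucleotides, DNA, non-nucleic residues).
#' @exportClass RNAStructure
setClass("RNAStructure", representation(
  structureId = "character", resolution = "numeric", method = "character",
  nModels = "integer", nucleotides = "list", skipped = "integer"
))

setValidity("RNAStructure", function(object) {
  if (!is.na(object@resolution) && object@resolution <= 0)
    return("resolution, when present, must be > 0")
  ok <- vapply(object@nucleotides, function(nt)
    is.list(nt) && all(c("chain", "seq", "base", "atoms") %in% names(nt)),
    logical(1L))
  if (!all(ok)) return("malformed nucleotide record")
  TRUE
})

setMethod("show", "RNAStructure", function(object) {
  cat(sprintf("RNAStructure %s: %d nucleotide(s), %d model(s)",
              object@structureId, length(object@nucleotides), object@nModels))
  if (!is.na(object@resolution))
    cat(sprintf(", resolution %.2f A", object@resolution))
  cat("\n")
  if (length(object@skipped) && any(object@skipped > 0)) {
    sk <- object@skipped[object@skipped > 0]
    cat("  skipped:", paste(sprintf("%s=%d", names(sk), sk), collapse = ", "), "\n")
  }
})

#' Symbolic motif query
#'
#' A query over n ordered nucleotide nodes: per-node base masks ("N" = any),
#' chain-continuity ("next") edges, and per-edge base-pair, lone-pair...pi,
#' and stacking constraints plus per-node glycosidic constraints.
#'
#' @slot nNodes number of nodes.
#' @slot baseMasks list of allowed base sets per node.
#' @slot nextEdges integer matrix, one row per covalent 5'->3' adjacency.
#' @slot pairConstraints list of list(i, j, spec) base-pair constraints.
#' @slot lppiConstraints list of list(i, j, spec) directional contact
#'   constraints (spec in the text grammar, e.g. "sO4'3").
#' @slot stackConstraints list of list(i, j, spec) face-face constraints.
#' @slot chiConstraints character vector ("syn", "anti" or "any") per node.
#' @slot puckerConstraints character vector (a pucker class or "any") per
#'   node.
#' @exportClass MotifQuery
setClass("MotifQuery", representation(
  nNodes = "integer", baseMasks = "list", nextEdges = "matrix",
  pairConstraints = "list", lppiConstraints = "list",
  stackConstraints = "list", chiConstraints = "character",
  puckerConstraints = "character"
))

setValidity("MotifQuery", function(object) {
  n <- object@nNodes
  idx <- c(object@nextEdges,
           unlist(lapply(c(object@pairConstraints, object@lppiConstraints,
                           object@stackConstraints),
                         function(x) c(x$i, x$j))))
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    return("constraint references a node index out of range")
  if (length(object@baseMasks) != n) return("one base mask per node required")
  if (length(object@chiConstraints) != n)
    return("one chi constraint per node required")
  if (length(object@puckerConstraints) != n)
    return("one pucker constraint per node required")
  TRUE
})

setMethod("show", "MotifQuery", function(object) {
  cat(sprintf("MotifQuery: %d nodes, masks %s, %d next edge(s)\n",
              object@nNodes,
              paste(vapply(object@baseMasks, function(b)
                if (length(b) == 4L) "N" else paste(b, collapse = ""),
                character(1L)), collapse = " "),
              nrow(object@nextEdges)))
  for (p in object@pairConstraints)
    cat(sprintf("  pair  nt%d-nt%d: %s\n", p$i, p$j, p$spec))
  for (p in object@lppiConstraints)
    cat(sprintf("  lp-pi nt%d-nt%d: %s\n", p$i, p$j, p$spec))
  for (p in object@stackConstraints)
    cat(sprintf("  stack nt%d-nt%d: %s\n", p$i, p$j, p$spec))
})

#' Motif search hits
#'
#' Result container of \code{\link{runQuery}} and the canned finders: a hit
#' table (structure id, model, ordered node keys, sequence string) plus the
#' per-hit node keys used to retrieve coordinates for superposition.
#'
#' @slot table data.frame with one row per hit.
#' @slot nodeKeys list of character vectors of node keys, one per hit.
#' @slot nNodes nodes per hit.
#' @exportClass MotifHits
setClass("MotifHits", representation(
  table = "data.frame", nodeKeys = "list", nNodes = "integer"
))

setMethod("show", "MotifHits", function(object) {
  cat(sprintf("MotifHits: %d hit(s) of %d node(s)\n",
              nrow(object@table), object@nNodes))
  if (nrow(object@table)) print(utils::head(object@table, 10L))
})

#' Number of motif hits
#' @param x a \code{MotifHits} object.
#' @export
setMethod("length", "MotifHits", function(x) nrow(x@table))

#' Hit table accessor
#' @param hits a \code{MotifHits} object.
#' @return data.frame of hits.
#' @export
hitTable <- function(hits) {
  stopifnot(is(hits, "MotifHits"))
  hits@table
}
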