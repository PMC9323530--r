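# Lightweight per-residue records. A record is a plain list (class
# "NucleotideRecord") so that structures with thousands of residues stay
# cheap; the heavyweight containers (RNAStructure, BaseFrame, ...) are S4.

#' Create a nucleotide record
#'
#' One RNA residue of one model: identity plus named atom coordinates,
#' occupancies and altloc identifiers. Atom names accept either the Unicode
#' prime or the ASCII apostrophe and are stored with the apostrophe.
#'
#' @param base base type, one of A, C, G, U.
#' @param atoms numeric matrix with 3 columns and atom names as rownames.
#' @param chain chain identifier.
#' @param seq author residue number.
#' @param icode insertion code ("" when absent).
#' @param model model number (>= 1).
#' @param structureId parent structure identifier.
#' @param occ named occupancy vector (defaults to 1 for every atom).
#' @param altloc named altloc identifier vector (defaults to "").
#' @return a \code{NucleotideRecord} (list).
#' @examples
#' nt <- buildNucleotide("G", chi = 60, puckerP = 18)
#' ntKey(nt)
#' @export
nucleotideRecord <- function(base, atoms, chain = "A", seq = 1L, icode = "",
                             model = 1L, structureId = "XXXX",
                             occ = NULL, altloc = NULL) {
  stopifnot(base %in% .rnaBases, is.matrix(atoms), ncol(atoms) == 3L,
            !is.null(rownames(atoms)))
  rownames(atoms) <- .asciiName(rownames(atoms))
  if (is.null(occ)) occ <- stats::setNames(rep(1, nrow(atoms)), rownames(atoms))
  if (is.null(altloc)) altloc <- stats::setNames(rep("", nrow(atoms)), rownames(atoms))
  structure(list(structureId = structureId, model = as.integer(model),
                 chain = chain, seq = as.integer(seq), icode = icode,
                 base = base, atoms = atoms, occ = occ, altloc = altloc),
            class = "NucleotideRecord")
}

#' Residue key of a nucleotide record
#'
#' Keys follow author numbering: \code{seq[icode]:chain} with a leading
#' \code{model/} prefix when the model is not 1 (e.g. \code{1692:a}).
#'
#' @param nt a nucleotide record.
#' @return character key.
#' @export
ntKey <- function(nt) {
  key <- sprintf("%d%s:%s", nt$seq, nt$icode, nt$chain)
  if (nt$model != 1L) key <- sprintf("%d/%s", nt$model, key)
  key
}

#' @export
print.NucleotideRecord <- function(x, ...) {
  cat(sprintf("NucleotideRecord %s %s (%s): %d atoms\n",
              x$base, ntKey(x), x$structureId, nrow(x$atoms)))
  invisible(x)
}

# Coordinate of one atom (NULL when absent).
.atomXYZ <- function(nt, name) {
  name <- .asciiName(name)
  if (!name %in% rownames(nt$atoms)) return(NULL)
  nt$atoms[name, ]
}

.hasAtoms <- function(nt, names) all(.asciiName(names) %in% rownames(nt$atoms))

#' Is a record annotatable?
#'
#' TRUE when all base ring atoms plus C1' are present, i.e. a base frame can
#' be computed and the residue can take part in annotations.
#'
#' @param nt a nucleotide record.
#' @export
isAnnotatable <- function(nt) {
  .hasAtoms(nt, c(.ringAtoms(nt$base), "C1'"))
}

# Apply a rigid motion (rotation R about `pivot`, then translation `shift`)
# to all atoms of a record.
.transformRecord <- function(nt, R = diag(3), pivot = c(0, 0, 0),
                             shift = c(0, 0, 0)) {
  nt$atoms <- sweep(sweep(nt$atoms, 2L, pivot) %*% t(R), 2L,
                    pivot + shift, "+")
  nt
}

#' Nucleotide records of a structure
#' @param x an \code{RNAStructure}.
#' @return list of nucleotide records.
#' @export
nucleotides <- function(x) {
  stopifnot(is(x, "RNAStructure"))
  x@nucleotides
}

#' Structure metadata
#' @param x an \code{RNAStructure}.
#' @return list with structureId, resolution, method, nModels.
#' @export
structureMeta <- function(x) {
  stopifnot(is(x, "RNAStructure"))
  list(structureId = x@structureId, resolution = x@resolution,
       method = x@method, nModels = x@nModels)
}

#' Assemble an RNAStructure from nucleotide records
#'
#' Used by the fixture builders and anywhere records are constructed in code
#' rather than parsed from a file.
#'
#' @param records list of nucleotide records.
#' @param structureId identifier stored in the container and in each record.
#' @param resolution optional resolution (Angstrom).
#' @param method optional experimental method string.
#' @return an \code{RNAStructure}.
#' @export
asRNAStructure <- function(records, structureId = "FIXTURE",
                           resolution = NA_real_, method = "") {
  records <- lapply(records, function(nt) { nt$structureId <- structureId; nt })
  nmod <- if (length(records))
    max(vapply(records, function(nt) nt$model, integer(1L))) else 1L
  new("RNAStructure", structureId = structureId,
      resolution = as.numeric(resolution), method = method,
      nModels = as.integer(nmod), nucleotides = records,
      skipped = stats::setNames(integer(0), character(0)))
}
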