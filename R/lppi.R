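# Lone-pair...pi (oxygen...pi) contact annotation: true (sO...) and near
# (nsO...) contacts between backbone oxygens and nucleobase faces, plus the
# text-constraint grammar used in symbolic queries.

.lppiCols <- c("structure_id", "model", "base_nt", "oxygen_nt", "base_type",
               "oxygen_atom", "face", "z", "x", "y", "ring", "category",
               "base_first", "oxygen_first")

.emptyLpPi <- function() {
  df <- data.frame(structure_id = character(), model = integer(),
                   base_nt = character(), oxygen_nt = character(),
                   base_type = character(), oxygen_atom = character(),
                   face = integer(), z = numeric(), x = numeric(),
                   y = numeric(), ring = integer(), category = character(),
                   base_first = character(), oxygen_first = character(),
                   stringsAsFactors = FALSE)
  df[, .lppiCols]
}

#' Parse a lone-pair...pi constraint string
#'
#' Grammar: optional "n" (near only) or "n+" (near and true) prefix; "s";
#' an optional face digit (3 or 5) either directly after "s" (base-first
#' reading, e.g. \code{s3O4'}) or after the oxygen token (oxygen-first
#' reading, e.g. \code{sO4'3}); an oxygen token among O, OP, OP1, OP2, O2',
#' O3', O4', O5' (O and OP are generic; the Unicode prime and the ASCII
#' apostrophe are both accepted).
#'
#' @param text constraint string.
#' @return list with \code{category} ("true", "near" or "both"), \code{face}
#'   (3, 5 or NA for either), \code{oxygens} (expanded atom-name set) and
#'   \code{direction} ("base_first" or "oxygen_first").
#' @examples
#' parseLpPiConstraint("n+sO4'3")
#' @export
parseLpPiConstraint <- function(text) {
  s <- .asciiName(text)
  pos <- 1L
  fail <- function(p, why) stop(structure(
    class = c("zmotifParseError", "error", "condition"),
    list(message = sprintf(
      "malformed lp...pi constraint \"%s\" at position %d: %s", text, p, why),
      call = NULL)))
  category <- "true"
  if (startsWith(s, "n+")) { category <- "both"; pos <- 3L }
  else if (startsWith(s, "n")) { category <- "near"; pos <- 2L }
  rest <- substring(s, pos)
  if (!startsWith(rest, "s")) fail(pos, "expected \"s\"")
  pos <- pos + 1L
  rest <- substring(s, pos)
  face <- NA_integer_
  direction <- "oxygen_first"
  if (grepl("^[35]", rest)) {
    face <- as.integer(substring(rest, 1L, 1L))
    direction <- "base_first"
    pos <- pos + 1L
    rest <- substring(s, pos)
  }
  tokens <- c("OP1", "OP2", "OP", "O2'", "O3'", "O4'", "O5'", "O")
  tok <- NULL
  for (t in tokens) if (startsWith(rest, t)) { tok <- t; break }
  if (is.null(tok)) fail(pos, "expected an oxygen token")
  pos <- pos + nchar(tok)
  rest <- substring(s, pos)
  if (grepl("^[35]$", rest)) {
    if (direction == "base_first") fail(pos, "face digit given twice")
    face <- as.integer(rest)
    pos <- pos + 1L
    rest <- substring(s, pos)
  }
  if (nchar(rest)) fail(pos, sprintf("unexpected \"%s\"", rest))
  oxygens <- switch(tok, O = .lpOxygens, OP = c("OP1", "OP2"), tok)
  list(category = category, face = face, oxygens = oxygens,
       direction = direction)
}

#' Match an annotation against a constraint string
#'
#' Honours the near prefix (bare = true contacts only, "n" = near only,
#' "n+" = both), generic oxygen expansion (sO, sOP), and face wildcards (a
#' string without a face digit matches either face). The two directional
#' renderings of one contact (\code{s3O4'} and \code{sO4'3}) denote the same
#' relation, so direction does not change matching at the single-annotation
#' level; it orients edges in \code{\link{runQuery}}.
#'
#' @param annotation one row of a contact table (or an equivalent list with
#'   \code{category}, \code{face}, \code{oxygen_atom}).
#' @param constraint constraint string.
#' @return logical.
#' @examples
#' ann <- list(category = "true", face = 3L, oxygen_atom = "O4'")
#' matchLpPiConstraint(ann, "sO")
#' @export
matchLpPiConstraint <- function(annotation, constraint) {
  p <- parseLpPiConstraint(constraint)
  okCat <- switch(p$category, both = TRUE,
                  near = annotation$category == "near",
                  annotation$category == "true")
  okFace <- is.na(p$face) || annotation$face == p$face
  okCat && okFace && .asciiName(annotation$oxygen_atom) %in% p$oxygens
}

# Contact strings for one annotation.
.lppiStrings <- function(atom, face, category) {
  disp <- .displayName(atom)
  pre <- if (category == "near") "n" else ""
  c(base_first = sprintf("%ss%d%s", pre, face, disp),
    oxygen_first = sprintf("%ss%s%d", pre, disp, face))
}

#' Annotate the lone-pair...pi contact of one ordered nucleotide pair
#'
#' At most one annotation per ordered (base, oxygen-owner) pair. Selection:
#' (1) among oxygens with zMin < |z| <= zMaxTrue projecting inside a ring
#' polygon, the smallest |z| wins (true contact); otherwise (2) among
#' oxygens with zMaxTrue < |z| <= zMaxNear inside a ring, the smallest |z|
#' wins (near); otherwise (3) among oxygens with |z| <= zMaxTrue inside an
#' expanded ellipse only, the projection closest to the base center wins
#' (near). Face 3 iff z > 0.
#'
#' @param baseNt nucleotide providing the base.
#' @param frame its \code{BaseFrame} (computed if NULL).
#' @param oxygenNt nucleotide providing the backbone oxygens.
#' @param params an \code{LpPiParameters}.
#' @return one-row data.frame, or NULL when there is no contact.
#' @export
annotateLpPi <- function(baseNt, oxygenNt, frame = NULL,
                         params = lpPiParameters()) {
  if (is.null(frame)) frame <- baseFrame(baseNt, expansion = params@ellipseExpansion)
  if (is.null(frame)) return(NULL)
  same <- identical(ntKey(baseNt), ntKey(oxygenNt)) &&
    identical(baseNt$model, oxygenNt$model)
  if (same && !params@includeIntra) return(NULL)
  atoms <- intersect(params@oxygenAtoms, rownames(oxygenNt$atoms))
  if (!length(atoms)) return(NULL)
  cand <- lapply(atoms, function(a) {
    xyz <- projectOntoFrame(frame, .atomXYZ(oxygenNt, a))
    loc <- locateProjection(frame, xyz[c("x", "y")])
    list(atom = a, x = xyz[["x"]], y = xyz[["y"]], z = xyz[["z"]],
         absz = abs(xyz[["z"]]), status = loc$status, ring = loc$ring)
  })
  pick <- function(sel, score) {
    if (!length(sel)) return(NULL)
    sel[[which.min(vapply(sel, score, numeric(1L)))]]
  }
  inRing <- Filter(function(c) c$status == "inside_ring", cand)
  best <- pick(Filter(function(c) c$absz > params@zMin &&
                        c$absz <= params@zMaxTrue, inRing),
               function(c) c$absz)
  category <- "true"
  if (is.null(best)) {
    best <- pick(Filter(function(c) c$absz > params@zMaxTrue &&
                          c$absz <= params@zMaxNear, inRing),
                 function(c) c$absz)
    category <- "near"
  }
  if (is.null(best)) {
    lateral <- Filter(function(c) c$status == "inside_expanded_ellipse" &&
                        c$absz <= params@zMaxTrue &&
                        (!params@nearLowerBound || c$absz > params@zMin), cand)
    best <- pick(lateral, function(c) sqrt(c$x^2 + c$y^2))
    category <- "near"
  }
  if (is.null(best)) return(NULL)
  face <- if (best$z > 0) 3L else 5L
  strs <- .lppiStrings(best$atom, face, category)
  data.frame(structure_id = baseNt$structureId, model = baseNt$model,
             base_nt = ntKey(baseNt), oxygen_nt = ntKey(oxygenNt),
             base_type = baseNt$base, oxygen_atom = best$atom,
             face = face, z = best$z, x = best$x, y = best$y,
             ring = best$ring, category = category,
             base_first = strs[["base_first"]],
             oxygen_first = strs[["oxygen_first"]],
             stringsAsFactors = FALSE)[, .lppiCols]
}

#' Scan a structure for lone-pair...pi contacts
#'
#' Examines every ordered nucleotide pair of the same model whose base
#' center lies within \code{pruneRadius} of some backbone oxygen of the
#' partner (non-lossy: |z| <= zMaxNear and the in-plane extent of the
#' expanded ellipses bound the contact distance well below 7 Angstrom).
#' Output rows are ordered by (model, base chain, base number, oxygen key).
#'
#' @param x an \code{RNAStructure} or a list of nucleotide records.
#' @param params an \code{LpPiParameters}.
#' @param near include near contacts (Cases 1 and 2); with
#'   \code{near = FALSE} only true contacts are returned.
#' @param pruneRadius candidate pruning radius in Angstrom.
#' @return data.frame of contacts (possibly empty) with fixed column order.
#' @examples
#' zs <- buildZStep()
#' scanLpPi(asRNAStructure(zs$records))$oxygen_first
#' @export
scanLpPi <- function(x, params = lpPiParameters(), near = TRUE,
                     pruneRadius = 7) {
  nts <- if (is(x, "RNAStructure")) nucleotides(x) else x
  if (!length(nts)) return(.emptyLpPi())
  ord <- order(vapply(nts, function(n) n$model, integer(1L)),
               vapply(nts, function(n) n$chain, character(1L)),
               vapply(nts, function(n) n$seq, integer(1L)),
               vapply(nts, function(n) n$icode, character(1L)))
  nts <- nts[ord]
  frames <- lapply(nts, function(nt)
    if (isAnnotatable(nt)) suppressWarnings(
      baseFrame(nt, expansion = params@ellipseExpansion)) else NULL)
  oxy <- lapply(nts, function(nt) {
    a <- intersect(params@oxygenAtoms, rownames(nt$atoms))
    nt$atoms[a, , drop = FALSE]
  })
  out <- list()
  for (i in seq_along(nts)) {
    if (is.null(frames[[i]])) next
    ctr <- frames[[i]]@center
    for (j in seq_along(nts)) {
      if (i == j && !params@includeIntra) next
      if (nts[[j]]$model != nts[[i]]$model) next
      om <- oxy[[j]]
      if (!nrow(om)) next
      if (min(sqrt(rowSums(sweep(om, 2L, ctr)^2))) > pruneRadius) next
      ann <- annotateLpPi(nts[[i]], nts[[j]], frame = frames[[i]],
                          params = params)
      if (!is.null(ann)) out[[length(out) + 1L]] <- ann
    }
  }
  if (!length(out)) return(.emptyLpPi())
  res <- do.call(rbind, out)
  if (!near) res <- res[res$category == "true", , drop = FALSE]
  rownames(res) <- NULL
  res
}
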