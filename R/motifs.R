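# Symbolic constraint engine and canned searches: Z-steps, Z_anti-steps and
# the Z-turn / Z_anti-turn loop signatures.

.parseError <- function(msg) {
  stop(structure(class = c("zmotifParseError", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Construct a symbolic motif query
#'
#' @param baseMasks character vector of per-node base masks: "N" (any) or a
#'   string of allowed bases (e.g. "U", "AG").
#' @param nextEdges matrix (or vector pairs) of covalent 5'->3' adjacencies;
#'   defaults to the full path 1-2, 2-3, ..., (n-1)-n.
#' @param pairConstraints,lppiConstraints,stackConstraints lists of
#'   \code{list(i, j, spec)} per-edge constraints; specs use the text
#'   grammar ("tSW UG", "n+tSW UG", "sO4'3", "s53", ...).
#' @param chiConstraints per-node "syn", "anti" or "any".
#' @param puckerConstraints per-node pucker class or "any".
#' @return a \code{MotifQuery}.
#' @examples
#' motifQuery(c("N", "U", "N", "N", "G", "N"),
#'            pairConstraints = list(list(i = 2, j = 5, spec = "tSW UG")))
#' @export
motifQuery <- function(baseMasks, nextEdges = NULL, pairConstraints = list(),
                       lppiConstraints = list(), stackConstraints = list(),
                       chiConstraints = NULL, puckerConstraints = NULL) {
  n <- length(baseMasks)
  masks <- lapply(baseMasks, function(m) {
    m <- toupper(m)
    if (m == "N") .rnaBases else {
      b <- strsplit(m, "")[[1L]]
      if (!all(b %in% .rnaBases))
        .parseError(sprintf("invalid base mask \"%s\"", m))
      b
    }
  })
  if (is.null(nextEdges)) {
    nextEdges <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    else matrix(integer(), 0L, 2L)
  }
  nextEdges <- matrix(as.integer(nextEdges), ncol = 2L)
  if (is.null(chiConstraints)) chiConstraints <- rep("any", n)
  if (is.null(puckerConstraints)) puckerConstraints <- rep("any", n)
  # validate constraint grammar up front (error before scanning)
  for (p in lppiConstraints) parseLpPiConstraint(p$spec)
  for (p in pairConstraints) .parsePairSpec(p$spec)
  for (p in stackConstraints) .parseStackSpec(p$spec)
  new("MotifQuery", nNodes = as.integer(n), baseMasks = masks,
      nextEdges = nextEdges, pairConstraints = pairConstraints,
      lppiConstraints = lppiConstraints, stackConstraints = stackConstraints,
      chiConstraints = chiConstraints,
      puckerConstraints = puckerConstraints)
}

# Pair constraint: whitespace-separated family alternatives with optional
# n/n+ prefixes, plus an optional two-letter base combination (N wildcard),
# e.g. "tSW ntSW UG" or "n+cWW".
.parsePairSpec <- function(spec) {
  toks <- strsplit(trimws(spec), "\\s+")[[1L]]
  fams <- list()
  combo <- NULL
  for (t in toks) {
    if (grepl("^[ACGUN]{2}$", t)) {
      if (!is.null(combo)) .parseError(sprintf(
        "pair constraint \"%s\": two base combinations", spec))
      combo <- strsplit(t, "")[[1L]]
    } else {
      m <- regmatches(t, regexec("^(n\\+|n)?([ct])([WHS])([WHS])$", t))[[1L]]
      if (!length(m)) .parseError(sprintf(
        "pair constraint \"%s\": bad token \"%s\"", spec, t))
      cat_ <- switch(m[2L], "n+" = "both", "n" = "near", "true")
      fam <- paste0(m[3L], m[4L], m[5L])
      if (cat_ == "both")
        fams <- c(fams, list(list(family = fam, near = FALSE)),
                  list(list(family = fam, near = TRUE)))
      else fams <- c(fams, list(list(family = fam, near = cat_ == "near")))
    }
  }
  if (!length(fams)) .parseError(sprintf(
    "pair constraint \"%s\": no family token", spec))
  list(fams = fams, combo = combo)
}

.parseStackSpec <- function(spec) {
  m <- regmatches(spec, regexec("^(n\\+|n)?s([35])([35])$", trimws(spec)))[[1L]]
  if (!length(m)) .parseError(sprintf("bad stack constraint \"%s\"", spec))
  list(category = switch(m[2L], "n+" = "both", "n" = "near", "true"),
       faces = paste0("s", m[3L], m[4L]))
}

# ---- per-structure annotation bundle with lazy pair caches -----------------

.bundle <- function(x, params = lpPiParameters()) {
  nts <- nucleotides(x)
  ord <- order(vapply(nts, function(n) n$model, integer(1L)),
               vapply(nts, function(n) n$chain, character(1L)),
               vapply(nts, function(n) n$seq, integer(1L)),
               vapply(nts, function(n) n$icode, character(1L)))
  nts <- nts[ord]
  n <- length(nts)
  conf <- lapply(nts, function(nt) list(
    chi = suppressWarnings(annotateGlycosidic(nt)),
    pucker = suppressWarnings(annotateSugarPucker(nt))))
  nxt <- rep(FALSE, max(0L, n - 1L))
  for (i in seq_len(max(0L, n - 1L))) {
    a <- nts[[i]]; b <- nts[[i + 1L]]
    if (a$model != b$model || a$chain != b$chain) next
    if (!(b$seq - a$seq) %in% c(0L, 1L)) next
    o3 <- .atomXYZ(a, "O3'"); p <- .atomXYZ(b, "P")
    if (is.null(o3) || is.null(p)) next
    nxt[i] <- .vnorm(o3 - p) <= 2.0
  }
  env <- new.env(parent = emptyenv())
  cache <- function(tag, i, j, fun) {
    key <- sprintf("%s_%d_%d", tag, i, j)
    if (!exists(key, envir = env)) assign(key, fun(), envir = env)
    get(key, envir = env)
  }
  list(structureId = x@structureId, nts = nts, conf = conf, nextOk = nxt,
       pair = function(i, j) cache("p", i, j, function()
         classifyBasePair(nts[[i]], nts[[j]])),
       stack = function(i, j) cache("s", i, j, function()
         classifyStacking(nts[[i]], nts[[j]])),
       lppi = function(baseI, oxyJ) cache("l", baseI, oxyJ, function()
         annotateLpPi(nts[[baseI]], nts[[oxyJ]], params = params)))
}

.matchPairConstraint <- function(bnd, i, j, spec) {
  ps <- .parsePairSpec(spec)
  p <- bnd$pair(i, j)
  if (is.null(p)) return(FALSE)
  if (!is.null(ps$combo)) {
    okCombo <- (ps$combo[1L] == "N" || p$base1 == ps$combo[1L]) &&
      (ps$combo[2L] == "N" || p$base2 == ps$combo[2L])
    if (!okCombo) return(FALSE)
  }
  any(vapply(ps$fams, function(f)
    f$family == p$family && f$near == p$near, logical(1L)))
}

.matchStackConstraint <- function(bnd, i, j, spec) {
  ps <- .parseStackSpec(spec)
  s <- bnd$stack(i, j)
  if (is.null(s)) return(FALSE)
  okCat <- switch(ps$category, both = TRUE, near = s$near, !s$near)
  okCat && s$faces == ps$faces
}

.matchLppiConstraint <- function(bnd, i, j, spec) {
  p <- parseLpPiConstraint(spec)
  # oxygen-first: node i owns the oxygen, node j the base
  ann <- if (p$direction == "base_first") bnd$lppi(i, j) else bnd$lppi(j, i)
  !is.null(ann) && matchLpPiConstraint(ann, spec)
}

#' Run a symbolic motif query
#'
#' Exhaustive enumeration anchored on the continuity edges: consecutive runs
#' satisfying all "next" edges are scanned first, then filtered by the base,
#' conformation, pair, stacking and contact constraints. Hit order is
#' deterministic (structure, then position); duplicate node tuples are
#' emitted once. Continuity edges must form the full path over the query
#' nodes (all canned queries are of this shape).
#'
#' @param query a \code{MotifQuery}.
#' @param structures an \code{RNAStructure} or list of them.
#' @param params contact parameters used for lp...pi constraints.
#' @param resolutionMax optional resolution cutoff (Angstrom); structures
#'   without a stated resolution are excluded with a message.
#' @return a \code{MotifHits} object.
#' @export
runQuery <- function(query, structures, params = lpPiParameters(),
                     resolutionMax = NULL) {
  validObject(query)
  if (is(structures, "RNAStructure")) structures <- list(structures)
  n <- query@nNodes
  path <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  else matrix(integer(), 0L, 2L)
  if (!identical(query@nextEdges[order(query@nextEdges[, 1L]), , drop = FALSE],
                 path))
    stop("only full-path continuity queries are supported")
  if (!is.null(resolutionMax)) {
    res <- vapply(structures, function(s) s@resolution, numeric(1L))
    drop <- is.na(res)
    if (any(drop)) message(sprintf(
      "%d structure(s) without a stated resolution excluded", sum(drop)))
    structures <- structures[!drop & res <= resolutionMax]
  }
  rows <- list(); keys <- list()
  for (s in structures) {
    bnd <- .bundle(s, params)
    m <- length(bnd$nts)
    if (m < n) next
    for (start in seq_len(m - n + 1L)) {
      w <- start:(start + n - 1L)
      if (n > 1L && !all(bnd$nextOk[w[-n]])) next
      okBase <- all(vapply(seq_len(n), function(k)
        bnd$nts[[w[k]]]$base %in% query@baseMasks[[k]], logical(1L)))
      if (!okBase) next
      okChi <- all(vapply(seq_len(n), function(k) {
        want <- query@chiConstraints[k]
        if (want == "any") return(TRUE)
        g <- bnd$conf[[w[k]]]$chi
        !is.null(g) && g$cls == want
      }, logical(1L)))
      if (!okChi) next
      okPuck <- all(vapply(seq_len(n), function(k) {
        want <- query@puckerConstraints[k]
        if (want == "any") return(TRUE)
        p <- bnd$conf[[w[k]]]$pucker
        !is.null(p) && p$cls == want
      }, logical(1L)))
      if (!okPuck) next
      okPair <- all(vapply(query@pairConstraints, function(p)
        .matchPairConstraint(bnd, w[p$i], w[p$j], p$spec), logical(1L)))
      if (!okPair) next
      okStack <- all(vapply(query@stackConstraints, function(p)
        .matchStackConstraint(bnd, w[p$i], w[p$j], p$spec), logical(1L)))
      if (!okStack) next
      okLppi <- all(vapply(query@lppiConstraints, function(p)
        .matchLppiConstraint(bnd, w[p$i], w[p$j], p$spec), logical(1L)))
      if (!okLppi) next
      ntw <- bnd$nts[w]
      k <- vapply(ntw, ntKey, character(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = bnd$structureId, model = ntw[[1L]]$model,
        chain = ntw[[1L]]$chain,
        nodes = paste(k, collapse = ","),
        sequence = paste(vapply(ntw, function(x) x$base, character(1L)),
                         collapse = ""),
        stringsAsFactors = FALSE)
      keys[[length(keys) + 1L]] <- k
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), model = integer(),
               chain = character(), nodes = character(),
               sequence = character(), stringsAsFactors = FALSE)
  dup <- duplicated(paste(tab$structure_id, tab$nodes))
  new("MotifHits", table = tab[!dup, , drop = FALSE], nodeKeys = keys[!dup],
      nNodes = as.integer(n))
}

# ---- canned searches -------------------------------------------------------

#' Find Z-steps
#'
#' Strict signature: two consecutive nucleotides with the 5'-nucleobase in
#' anti, the 5'-sugar in C2'-endo, the 3'-nucleotide in syn and an sO4'3
#' contact of the 5'-ribose O4' on the 3'-face of the 3'-base. The
#' \code{stack_fallback} mode replaces the syn constraint by an s53 stacking
#' constraint, the recommended alternative when chi is borderline.
#'
#' @param x an \code{RNAStructure} or list of them.
#' @param mode "strict" or "stack_fallback".
#' @param params contact parameters.
#' @param resolutionMax optional resolution cutoff.
#' @return a \code{MotifHits}; the sequence column is reported NpN-style in
#'   \code{hitTable(...)$step}.
#' @examples
#' zh <- buildZHelix(2)
#' hitTable(findZSteps(asRNAStructure(zh$records)))$step
#' @export
findZSteps <- function(x, mode = c("strict", "stack_fallback"),
                       params = lpPiParameters(), resolutionMax = NULL) {
  mode <- match.arg(mode)
  q <- motifQuery(c("N", "N"),
                  lppiConstraints = list(list(i = 1L, j = 2L, spec = "sO4'3")),
                  chiConstraints = c("anti", if (mode == "strict") "syn" else "any"),
                  puckerConstraints = c("C2'-endo", "any"),
                  stackConstraints = if (mode == "stack_fallback")
                    list(list(i = 1L, j = 2L, spec = "s53")) else list())
  hits <- runQuery(q, x, params = params, resolutionMax = resolutionMax)
  if (nrow(hits@table))
    hits@table$step <- sub("(.)(.)", "\\1p\\2", hits@table$sequence)
  hits
}

#' Find Z_anti-steps
#'
#' Two consecutive nucleotides with an sO4'5 contact (5'-ribose O4' on the
#' 5'-face of the 3'-base) and the 3'-nucleobase in anti; the fallback mode
#' uses an s55 stacking constraint instead of the chi constraint.
#'
#' @inheritParams findZSteps
#' @export
findZAntiSteps <- function(x, mode = c("strict", "stack_fallback"),
                           params = lpPiParameters(), resolutionMax = NULL) {
  mode <- match.arg(mode)
  q <- motifQuery(c("N", "N"),
                  lppiConstraints = list(list(i = 1L, j = 2L, spec = "sO4'5")),
                  chiConstraints = c("any", if (mode == "strict") "anti" else "any"),
                  stackConstraints = if (mode == "stack_fallback")
                    list(list(i = 1L, j = 2L, spec = "s55")) else list())
  hits <- runQuery(q, x, params = params, resolutionMax = resolutionMax)
  if (nrow(hits@table))
    hits@table$step <- sub("(.)(.)", "\\1p\\2", hits@table$sequence)
  hits
}

# Template definitions for the six-node loop queries. Node numbering is
# n-X-N-N-Y-n; the closing pair sits on nodes (2, 5).
.zturnTemplates <- list(
  UNNG = list(masks = c("N", "U", "N", "N", "G", "N"), pair = "tSW UG",
              lppi = "sO4'3", anti = c(3L, 4L)),
  GNNA = list(masks = c("N", "G", "N", "N", "A", "N"), pair = "tSW GA",
              lppi = "sO4'3", anti = c(3L, 4L)),
  CNNG = list(masks = c("N", "C", "N", "N", "G", "N"), pair = "tSW CG",
              lppi = "sO4'3", anti = c(3L, 4L)),
  zanti_CNNG = list(masks = c("N", "C", "N", "N", "G", "N"), pair = "cWW CG",
                    lppi = "sO4'5", anti = integer(), chi5 = "anti")
)

#' Find Z-turn / Z_anti-turn loops
#'
#' Canned six-node queries (n-X-N-N-Y-n with five "next" edges). The loose
#' form imposes only the sequence mask and the closing pair (tSW U2-G5,
#' G2-A5 or C2-G5 per template); the strict form adds the nt4-nt5 sO4'3
#' contact and anti constraints on nt3 and nt4, the combination that
#' separates well-modelled loops from dubious ones. The zanti_CNNG template
#' is the Z_anti-turn query: cWW C2=G5 pair, nt4-nt5 sO4'5 and G5 in anti
#' (identical in both strictness modes).
#'
#' @param x an \code{RNAStructure} or list of them.
#' @param template "UNNG", "GNNA", "CNNG", "zanti_CNNG" or "custom".
#' @param strictness "loose" or "strict".
#' @param query the \code{MotifQuery} to run when \code{template = "custom"}.
#' @param params contact parameters.
#' @param resolutionMax optional resolution cutoff.
#' @return a \code{MotifHits}.
#' @examples
#' zt <- buildUNCGZTurn()
#' length(findZTurns(asRNAStructure(zt$records), "UNNG", "strict"))
#' @export
findZTurns <- function(x, template = c("UNNG", "GNNA", "CNNG", "zanti_CNNG",
                                       "custom"),
                       strictness = c("loose", "strict"), query = NULL,
                       params = lpPiParameters(), resolutionMax = NULL) {
  template <- match.arg(template)
  strictness <- match.arg(strictness)
  if (template == "custom") {
    if (is.null(query)) stop("custom template requires a query")
    return(runQuery(query, x, params = params, resolutionMax = resolutionMax))
  }
  tm <- .zturnTemplates[[template]]
  chi <- rep("any", 6L)
  lppi <- list()
  if (template == "zanti_CNNG") {
    chi[5L] <- tm$chi5
    lppi <- list(list(i = 4L, j = 5L, spec = tm$lppi))
  } else if (strictness == "strict") {
    chi[tm$anti] <- "anti"
    lppi <- list(list(i = 4L, j = 5L, spec = tm$lppi))
  }
  q <- motifQuery(tm$masks,
                  pairConstraints = list(list(i = 2L, j = 5L, spec = tm$pair)),
                  lppiConstraints = lppi, chiConstraints = chi)
  runQuery(q, x, params = params, resolutionMax = resolutionMax)
}

#' Mutual similarity matrix of motif hits
#'
#' Symmetric matrix of node-matched RMSD values: for each pair of hits the
#' base heavy atoms plus C1' of corresponding nodes are superposed by an
#' optimal rigid fit and the RMSD is reported (a plain structural-similarity
#' substitute for a search tool's discrepancy score, and labelled as RMSD in
#' all outputs).
#'
#' @param hits a \code{MotifHits} with at least 2 hits, equal node counts.
#' @param structures the structure(s) the hits came from.
#' @return numeric matrix (Angstrom), zero diagonal.
#' @export
mutualRMSDMatrix <- function(hits, structures) {
  stopifnot(is(hits, "MotifHits"))
  if (length(hits) < 2L) stop("need at least 2 hits")
  if (is(structures, "RNAStructure")) structures <- list(structures)
  names(structures) <- vapply(structures, function(s) s@structureId,
                              character(1L))
  getCoords <- function(h) {
    sid <- hits@table$structure_id[h]
    s <- structures[[sid]]
    if (is.null(s)) stop(sprintf("structure %s not supplied", sid))
    keymap <- stats::setNames(nucleotides(s),
                              vapply(nucleotides(s), ntKey, character(1L)))
    lapply(hits@nodeKeys[[h]], function(k) {
      nt <- keymap[[k]]
      sel <- intersect(c(.baseHeavyAtoms[[nt$base]], "C1'"),
                       rownames(nt$atoms))
      nt$atoms[sel, , drop = FALSE]
    })
  }
  coords <- lapply(seq_len(length(hits)), getCoords)
  nh <- length(coords)
  M <- matrix(0, nh, nh)
  for (a in seq_len(nh - 1L)) for (b in (a + 1L):nh) {
    A <- list(); B <- list()
    for (k in seq_len(hits@nNodes)) {
      common <- intersect(rownames(coords[[a]][[k]]),
                          rownames(coords[[b]][[k]]))
      A[[k]] <- coords[[a]][[k]][common, , drop = FALSE]
      B[[k]] <- coords[[b]][[k]][common, , drop = FALSE]
    }
    A <- do.call(rbind, A); B <- do.call(rbind, B)
    idx <- seq_len(3L * nrow(A))
    fitted <- bio3d::fit.xyz(fixed = as.numeric(t(A)),
                             mobile = as.numeric(t(B)),
                             fixed.inds = idx, mobile.inds = idx)
    M[a, b] <- M[b, a] <- sqrt(mean(rowSums(
      (matrix(fitted, ncol = 3L, byrow = TRUE) - A)^2)))
  }
  M
}

#' Survey-level sanity checks on Z-step hits
#'
#' Checks the survey-level expectations on any scanned corpus: CpG should be
#' the modal Z-step sequence and no CpC Z-step should be reported. Violations
#' raise warnings, never errors.
#'
#' @param hits a \code{MotifHits} from \code{\link{findZSteps}}.
#' @return list with the step-sequence counts and the two check outcomes.
#' @export
checkZStepSurvey <- function(hits) {
  tab <- hitTable(hits)
  counts <- if (nrow(tab)) sort(table(tab$step), decreasing = TRUE) else
    table(character())
  modalOk <- nrow(tab) == 0L || names(counts)[1L] == "CpG"
  noCpC <- !("CpC" %in% names(counts))
  if (!modalOk)
    warning("CpG is not the modal Z-step sequence in this corpus")
  if (!noCpC)
    warning("CpC Z-steps reported; expected none")
  list(counts = counts, modal_is_CpG = modalOk, no_CpC = noCpC)
}
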