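# mmCIF/PDB reading (via bio3d) into nucleotide records, the altloc /
# occupancy policy, and structure metadata (resolution, method, model count).

.waterResidues <- c("HOH", "DOD", "WAT", "H2O")

# Resolution / method / id metadata, scanned from the file header. bio3d
# does not expose these fields, so they are read from the text directly.
.scanMeta <- function(path, fmt) {
  lines <- readLines(path, warn = FALSE)
  num <- function(x) {
    m <- regmatches(x, regexpr("[0-9]+\\.?[0-9]*", x))
    if (length(m) && nzchar(m[1L])) as.numeric(m[1L]) else NA_real_
  }
  resolution <- NA_real_
  method <- ""
  id <- toupper(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                    ignore.case = TRUE))
  if (fmt == "pdb") {
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r)) resolution <- num(sub(".*RESOLUTION\\.?", "", r[1L]))
    e <- grep("^EXPDTA", lines, value = TRUE)
    if (length(e)) method <- trimws(substring(e[1L], 11L))
    h <- grep("^HEADER", lines, value = TRUE)
    if (length(h) && nchar(h[1L]) >= 66L) {
      code <- trimws(substring(h[1L], 63L, 66L))
      if (nzchar(code)) id <- code
    }
  } else {
    for (key in c("_refine.ls_d_res_high", "_reflns.d_resolution_high",
                  "_em_3d_reconstruction.resolution")) {
      r <- grep(key, lines, fixed = TRUE, value = TRUE)
      r <- r[!grepl("\\?\\s*$", r)]
      if (length(r) && !is.na(num(sub(key, "", r[1L], fixed = TRUE)))) {
        resolution <- num(sub(key, "", r[1L], fixed = TRUE))
        break
      }
    }
    e <- grep("_exptl.method", lines, fixed = TRUE, value = TRUE)
    if (length(e))
      method <- gsub("['\"]", "", trimws(sub("_exptl.method", "", e[1L],
                                             fixed = TRUE)))
    d <- grep("^data_", lines, value = TRUE)
    if (length(d) && nzchar(sub("^data_", "", d[1L])))
      id <- toupper(sub("^data_", "", d[1L]))
  }
  list(structureId = id, resolution = resolution, method = method)
}

#' Read an RNA-containing structure
#'
#' Parses an mmCIF or PDB file into one nucleotide record per RNA residue
#' per requested model. Non-RNA residues are skipped with per-category
#' counts: DNA residues (unless \code{dnaAsRNA} maps them onto their ribo
#' counterparts for contact annotation), modified nucleotides (recognised by
#' a C1' atom under a non-standard residue name), waters and everything
#' else. When an atom carries alternate locations the lexicographically
#' first altloc is retained and the occupancy recorded; the occupancy-based
#' exclusion policy is applied separately by \code{\link{filterAltlocs}}.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @param model model number(s) to keep, or "all"; default 1.
#' @param dnaAsRNA annotate DNA residues as their ribo counterparts
#'   (DT is treated as U; the methyl is ignored).
#' @return an \code{RNAStructure}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          model = 1L, dnaAsRNA = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  meta <- .scanMeta(path, format)
  df <- parsed$atom
  df$insert[is.na(df$insert)] <- ""
  df$alt[is.na(df$alt)] <- ""
  df$o[is.na(df$o)] <- 1
  nModels <- max(1L, nrow(parsed$xyz))
  models <- if (identical(model, "all")) seq_len(nModels) else as.integer(model)
  if (any(models > nModels))
    stop(sprintf("model %d requested but file has %d model(s)",
                 max(models), nModels))
  resid <- df$resid
  isRNA <- resid %in% .rnaBases
  isDNA <- resid %in% .dnaResidues
  isWater <- resid %in% .waterResidues
  skipped <- c(dna = 0L, modified = 0L, water = 0L, other = 0L)
  resKeyAll <- paste(df$chain, df$resno, df$insert, sep = "|")
  skipped["water"] <- length(unique(resKeyAll[isWater]))
  useDNA <- dnaAsRNA & isDNA
  if (!dnaAsRNA) skipped["dna"] <- length(unique(resKeyAll[isDNA]))
  restKey <- unique(resKeyAll[!isRNA & !isDNA & !isWater])
  if (length(restKey)) {
    hasC1 <- vapply(restKey, function(k) {
      rows <- resKeyAll == k & !isRNA & !isDNA & !isWater
      any(df$elety[rows] %in% c("C1'", "C1*"))
    }, logical(1L))
    skipped["modified"] <- sum(hasC1)
    skipped["other"] <- sum(!hasC1)
  }
  keep <- isRNA | useDNA
  if (!any(keep)) {
    warning(sprintf("no RNA residues found in %s", path))
    return(new("RNAStructure", structureId = meta$structureId,
               resolution = meta$resolution, method = meta$method,
               nModels = nModels, nucleotides = list(), skipped = skipped))
  }
  dnaMap <- c(DA = "A", DC = "C", DG = "G", DT = "U")
  records <- list()
  for (mdl in models) {
    coords <- matrix(parsed$xyz[mdl, ], ncol = 3L, byrow = TRUE)
    sub <- which(keep)
    resKey <- resKeyAll[sub]
    for (k in unique(resKey)) {
      rows <- sub[resKey == k]
      first <- rows[1L]
      base <- resid[first]
      if (base %in% .dnaResidues) base <- dnaMap[[base]]
      elety <- .asciiName(gsub("\\*", "'", gsub("^\"|\"$", "", df$elety[rows])))
      # keep the lexicographically first altloc per atom name
      ord <- order(elety, df$alt[rows])
      rows <- rows[ord]; elety <- elety[ord]
      firstOcc <- !duplicated(elety)
      rows <- rows[firstOcc]; elety <- elety[firstOcc]
      atoms <- coords[rows, , drop = FALSE]
      rownames(atoms) <- elety
      records[[length(records) + 1L]] <- nucleotideRecord(
        base, atoms, chain = df$chain[first], seq = df$resno[first],
        icode = df$insert[first], model = mdl,
        structureId = meta$structureId,
        occ = stats::setNames(df$o[rows], elety),
        altloc = stats::setNames(df$alt[rows], elety))
    }
  }
  new("RNAStructure", structureId = meta$structureId,
      resolution = meta$resolution, method = meta$method,
      nModels = nModels, nucleotides = records, skipped = skipped)
}

#' Apply the alternate-conformation occupancy policy
#'
#' Under \code{exclude_partial} (the default survey policy) any nucleotide
#' whose base-ring atoms or backbone oxygens carry occupancy < 1 is dropped
#' from annotation; under \code{keep_first} every record is retained (the
#' parser already kept the lexicographically first altloc), with a note.
#' The operation is idempotent.
#'
#' @param x an \code{RNAStructure} or list of records.
#' @param policy "exclude_partial" or "keep_first".
#' @return same type as the input, filtered.
#' @export
filterAltlocs <- function(x, policy = c("exclude_partial", "keep_first")) {
  policy <- match.arg(policy)
  nts <- if (is(x, "RNAStructure")) nucleotides(x) else x
  if (policy == "keep_first") {
    partial <- sum(vapply(nts, function(nt) any(nt$occ < 1), logical(1L)))
    if (partial)
      message(sprintf("%d nucleotide(s) retain first-altloc coordinates", partial))
    out <- nts
  } else {
    out <- Filter(function(nt) {
      watch <- intersect(c(.ringAtoms(nt$base), .lpOxygens), names(nt$occ))
      all(nt$occ[watch] >= 1)
    }, nts)
  }
  if (is(x, "RNAStructure")) {
    x@nucleotides <- out
    x
  } else out
}

#' Read a representative-set list file
#'
#' Plain text, one \code{PDBID|model|chain} entry per line; blank lines and
#' lines starting with \code{#} are ignored.
#'
#' @param path list file.
#' @return data.frame with pdb_id, model, chain.
#' @export
readStructureList <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) != 3L
  if (any(bad)) .parseError(sprintf(
    "bad representative-set entry at line %d: \"%s\"",
    which(bad)[1L], lines[which(bad)[1L]]))
  data.frame(pdb_id = toupper(vapply(parts, `[`, character(1L), 1L)),
             model = as.integer(vapply(parts, `[`, character(1L), 2L)),
             chain = vapply(parts, `[`, character(1L), 3L),
             stringsAsFactors = FALSE)
}
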