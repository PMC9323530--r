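test_that("a minimal mmCIF with one G residue parses into one record", {
  nt <- idealNt("G")
  path <- withr::local_tempfile(fileext = ".cif")
  writeStructure(list(nt), path, "mmcif")
  s <- suppressWarnings(readStructure(path))
  expect_length(nucleotides(s), 1L)
  expect_identical(nucleotides(s)[[1L]]$base, "G")
  expect_true(isAnnotatable(nucleotides(s)[[1L]]))
})

test_that("coordinates round-trip through PDB and mmCIF at format precision", {
  recs <- fixture("zstep")$records
  for (fmt in c("pdb", "mmcif")) {
    path <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    writeStructure(asRNAStructure(recs, "ZSTP"), path, fmt)
    s <- suppressWarnings(readStructure(path))
    expect_length(nucleotides(s), 2L)
    for (k in 1:2) {
      a0 <- recs[[k]]$atoms
      a1 <- nucleotides(s)[[k]]$atoms[rownames(a0), , drop = FALSE]
      expect_lt(max(abs(a0 - a1)), 1.5e-3)
    }
    # and the annotation survives the round trip
    expect_identical(scanLpPi(s)$oxygen_first, "sO4′3")
  }
})

test_that("a protein-only file yields an empty record list with a warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O",
    "END"), path)
  expect_warning(s <- readStructure(path), "no RNA residues")
  expect_length(nucleotides(s), 0L)
  expect_gte(sum(s@skipped), 1L)
})

test_that("resolution and method metadata are scanned from headers", {
  path <- withr::local_tempfile(fileext = ".pdb")
  nt <- idealNt("G")
  writeStructure(list(nt), path, "pdb")
  body <- readLines(path)
  writeLines(c(
    "HEADER    RIBOSOME                                01-JAN-21   9XYZ              ",
    "EXPDTA    ELECTRON MICROSCOPY",
    "REMARK   2 RESOLUTION.    1.98 ANGSTROMS.",
    body), path)
  s <- readStructure(path)
  meta <- structureMeta(s)
  expect_equal(meta$resolution, 1.98)
  expect_identical(meta$structureId, "9XYZ")
  expect_match(meta$method, "MICROSCOPY")

  cifPath <- withr::local_tempfile(fileext = ".cif")
  writeStructure(list(nt), cifPath, "mmcif")
  body <- readLines(cifPath)
  writeLines(c(body[1L], "_refine.ls_d_res_high    2.40", body[-1L]), cifPath)
  s2 <- suppressWarnings(readStructure(cifPath))
  expect_equal(structureMeta(s2)$resolution, 2.40)
})

test_that("partial occupancy on watched atoms drops the nucleotide", {
  recs <- fixture("zstep")$records
  recs[[1L]]$occ[["O4'"]] <- 0.5
  kept <- filterAltlocs(recs, "exclude_partial")
  expect_length(kept, 1L)
  expect_identical(kept[[1L]]$seq, 2L)
  # occupancy < 1 on an unwatched atom is not a reason to drop
  recs2 <- fixture("zstep")$records
  recs2[[1L]]$occ[["C5'"]] <- 0.5
  expect_length(filterAltlocs(recs2, "exclude_partial"), 2L)
})

test_that("filterAltlocs is idempotent and keep_first retains records", {
  recs <- fixture("zstep")$records
  recs[[1L]]$occ[["OP1"]] <- 0.4
  once <- filterAltlocs(recs, "exclude_partial")
  expect_identical(filterAltlocs(once, "exclude_partial"), once)
  expect_length(suppressMessages(filterAltlocs(recs, "keep_first")), 2L)
})

test_that("altloc duplicates resolve to the lexicographically first altloc", {
  nt <- idealNt("G")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(list(nt), path, "pdb")
  lines <- readLines(path)
  o4 <- grep(" O4' ", lines, fixed = TRUE, value = TRUE)[1L]
  altA <- sub("^(.{16}).", "\\1A", o4)
  altB <- sub("^(.{16}).", "\\1B", o4)
  substr(altB, 31L, 38L) <- sprintf("%8.3f", 99.0)
  lines <- append(setdiff(lines, o4), c(altA, altB),
                  after = grep(" C1' ", lines, fixed = TRUE)[1L])
  writeLines(lines, path)
  s <- readStructure(path)
  rec <- nucleotides(s)[[1L]]
  expect_identical(unname(rec$altloc[["O4'"]]), "A")
  expect_lt(abs(rec$atoms["O4'", 1L] - nt$atoms["O4'", 1L]), 1e-2)
})

test_that("representative-set lists parse and reject malformed lines", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "7K00|1|A", "3U4M|1|B"), path)
  df <- readStructureList(path)
  expect_identical(df$pdb_id, c("7K00", "3U4M"))
  expect_identical(df$chain, c("A", "B"))
  writeLines("7K00;1;A", path)
  expect_error(readStructureList(path), "line 1")
})
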