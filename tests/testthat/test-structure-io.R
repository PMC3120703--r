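# Multi-model PDB reading and writing.

test_that("write-read round trip preserves identity and coordinates", {
  b <- makeBundle(bundleSpec(regions = data.frame(n = 12, kind = "rigid",
                                                  sigma = 0.2),
                             nConf = 4, seed = 21))
  f <- tempfile(fileext = ".pdb")
  writeBundle(b, f)
  b2 <- readBundle(f)
  expect_equal(nConformers(b2), 4L)
  expect_equal(residueTable(b2), residueTable(b))
  expect_equal(atomTable(b2)$atom, atomTable(b)$atom)
  expect_equal(coordArray(b2), coordArray(b), tolerance = 1e-3)
  # twice around: byte-identical coordinates at format precision
  f2 <- tempfile(fileext = ".pdb")
  writeBundle(b2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a single-model file is rejected", {
  b <- makeBundle(bundleSpec(regions = data.frame(n = 6, kind = "rigid",
                                                  sigma = 0.1),
                             nConf = 2, seed = 1))
  f <- tempfile(fileext = ".pdb")
  writeBundle(b, f)
  lines <- readLines(f)
  one <- lines[1:(grep("^ENDMDL", lines)[1])]
  f1 <- tempfile(fileext = ".pdb")
  writeLines(one, f1)
  expect_error(readBundle(f1), "insufficient conformers")
  expect_error(readBundle(f, modelLimit = 1), "insufficient conformers")
})

test_that("atoms missing from one model are dropped everywhere with a warning", {
  b <- makeBundle(bundleSpec(regions = data.frame(n = 8, kind = "rigid",
                                                  sigma = 0.1),
                             nConf = 3, seed = 2))
  f <- tempfile(fileext = ".pdb")
  writeBundle(b, f)
  lines <- readLines(f)
  # remove residue 5's CG from model 3 only
  hit <- grep("^ATOM.* CG .* {3}5 ", lines)
  expect_length(hit, 3L)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines[-hit[3]], f2)
  expect_warning(b2 <- readBundle(f2), "inconsistent models")
  # brute-force intersection of the per-model atom sets
  at <- atomTable(b)
  expected <- paste(at$resno, at$atom)[!(at$resno == 5 & at$atom == "CG")]
  expect_identical(paste(atomTable(b2)$resno, atomTable(b2)$atom), expected)
})

test_that("hydrogens, waters and altloc duplicates are handled on input", {
  mkline <- function(serial, name, resname, chain, resno, xyz, alt = " ",
                     occ = 1, el = substr(name, 1, 1)) {
    sprintf("ATOM  %5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, ifelse(nchar(name) >= 4, sprintf("%-4s", name),
                           sprintf(" %-3s", name)), alt, resname, chain, resno,
            xyz[1], xyz[2], xyz[3], occ, 0, el)
  }
  model <- function(k, caA = c(1, 1, 1)) c(
    sprintf("MODEL %8d", k),
    mkline(1, "N", "ALA", "A", 1, c(0, 0, 0)),
    mkline(2, "CA", "ALA", "A", 1, caA, alt = "A", occ = 0.4),
    mkline(3, "CA", "ALA", "A", 1, caA + 9, alt = "B", occ = 0.6),
    mkline(4, "C", "ALA", "A", 1, c(2, 0, 0)),
    mkline(5, "HA", "ALA", "A", 1, c(9, 9, 9), el = "H"),
    mkline(6, "N", "ALA", "A", 2, c(3, 0, 0)),
    mkline(7, "CA", "ALA", "A", 2, c(4, 0, 0)),
    mkline(8, "C", "ALA", "A", 2, c(5, 0, 0)),
    mkline(9, "O", "HOH", "A", 90, c(7, 7, 7), el = "O"),
    "ENDMDL")
  f <- tempfile(fileext = ".pdb")
  writeLines(c(model(1), model(2), "END"), f)
  b <- readBundle(f)
  at <- atomTable(b)
  expect_false(any(at$atom == "HA"))
  expect_false(any(at$resname == "HOH"))       # no CA -> dropped
  expect_equal(sum(at$atom == "CA" & at$resno == 1), 1L)
  # the occupancy-0.6 altloc B variant wins
  expect_equal(coordArray(b)[which(at$atom == "CA" & at$resno == 1), , 1],
               c(10, 10, 10))
})

test_that("reader agrees with bio3d on a clean multi-model file", {
  skip_if_not_installed("bio3d")
  b <- makeBundle(bundleSpec(regions = data.frame(n = 10, kind = "rigid",
                                                  sigma = 0.3),
                             nConf = 3, seed = 5))
  f <- tempfile(fileext = ".pdb")
  writeBundle(b, f)
  b2 <- readBundle(f)
  ref <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(dim(ref$xyz)[1], 3L)
  ours <- coordArray(b2)
  for (k in 1:3) {
    theirs <- matrix(ref$xyz[k, ], ncol = 3, byrow = TRUE)
    expect_equal(unname(ours[, , k]), unname(theirs), tolerance = 1e-6)
  }
})

test_that("writeSuperimposed aligns conformers and rejects empty selections", {
  spec <- rigidSpec(31, n = 12, nConf = 4)
  b <- makeBundle(spec)
  rep <- findResidueRanges(b)
  f <- tempfile(fileext = ".pdb")
  writeSuperimposed(b, rep, f)
  out <- readBundle(f)
  co <- coordArray(out)
  for (k in 2:4)
    expect_lt(max(abs(co[, , k] - co[, , 1])), 2e-3)  # format precision

  empty <- new("RangeResult", ranges = data.frame(), residues = integer(),
               nResidues = 0L, nGaps = 0L, rmsd = NA_real_,
               history = data.frame())
  expect_error(writeSuperimposed(b, empty, f), "empty selection")
})
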