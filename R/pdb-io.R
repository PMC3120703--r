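# Multi-model PDB input/output.
#
# The reader is deliberately strict about ensemble semantics: it requires at
# least two models, keeps for alternate locations the highest-occupancy
# variant (first on ties), ignores hydrogens and waters, drops residues
# without a CA atom, and intersects the atom sets of all models (with a
# warning) so that every conformer ends up with the identical composition.

pdbField <- function(lines, from, to) substring(lines, from, to)

parsePdbModel <- function(lines) {
  rec <- pdbField(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(NULL)
  name <- trimws(pdbField(lines, 13, 16))
  alt <- pdbField(lines, 17, 17)
  resname <- trimws(pdbField(lines, 18, 20))
  chain <- pdbField(lines, 22, 22)
  resno <- suppressWarnings(as.integer(pdbField(lines, 23, 26)))
  ins <- trimws(pdbField(lines, 27, 27))
  x <- as.numeric(pdbField(lines, 31, 38))
  y <- as.numeric(pdbField(lines, 39, 46))
  z <- as.numeric(pdbField(lines, 47, 54))
  occ <- suppressWarnings(as.numeric(pdbField(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(pdbField(lines, 77, 78)))
  # hydrogens/deuterium: element field if present, else first letter of the
  # atom name after stripping leading digits
  guess <- sub("^[0-9']*", "", name)
  isH <- ifelse(elem != "", elem %in% c("H", "D"),
                substring(guess, 1, 1) %in% c("H", "D"))
  df <- data.frame(chain = chain, resno = resno, ins = ins, resname = resname,
                   atom = name, alt = alt, occ = occ, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  df <- df[!isH & !is.na(df$resno) & df$resname != "HOH", , drop = FALSE]
  if (nrow(df) == 0L)
    return(NULL)
  # alternate locations: keep highest occupancy, first on ties
  key <- paste(df$chain, df$resno, df$ins, df$atom, sep = "\r")
  ord <- order(match(key, unique(key)), -df$occ)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resno, df$ins, df$atom, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a multi-model PDB file into a StructureBundle
#'
#' Parses a PDB file containing two or more MODEL records.  Hydrogens and
#' waters are ignored; for alternate locations the highest-occupancy variant
#' is kept (first on ties); residues without a CA atom (e.g. ligands) are
#' dropped.  If the models do not share the identical atom composition, atoms
#' absent from any model are dropped from all models with a warning; if no
#' common atoms remain an \code{"inconsistent models"} error is raised.
#'
#' @param path path to a PDB file with MODEL/ENDMDL records.
#' @param modelLimit optional positive integer; read at most this many models.
#' @return A [StructureBundle-class].
#' @examples
#' spec <- bundleSpec(regions = data.frame(n = 12, kind = "rigid", sigma = 0.1),
#'                    nConf = 3, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeBundle(makeBundle(spec), f)
#' b <- readBundle(f)
#' nConformers(b)
#' @seealso [writeBundle()], [writeSuperimposed()]
#' @export
readBundle <- function(path, modelLimit = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    models <- list(parsePdbModel(lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      ends <- c(ends, length(lines))
    models <- lapply(seq_along(starts), function(i)
      parsePdbModel(lines[(starts[i] + 1L):(ends[i] - 1L)]))
  }
  models <- Filter(Negate(is.null), models)
  if (!is.null(modelLimit))
    models <- head(models, modelLimit)
  if (length(models) < 2L)
    stop("insufficient conformers: need at least 2 models, got ", length(models))

  akey <- function(m) paste(m$chain, m$resno, m$ins, m$resname, m$atom, sep = "\r")
  common <- Reduce(intersect, lapply(models, akey))
  nAll <- length(unique(unlist(lapply(models, akey))))
  if (length(common) == 0L)
    stop("inconsistent models: no atom is present in every model")
  if (nAll > length(common))
    warning(sprintf("inconsistent models: dropped %d atom(s) absent from at least one model",
                    nAll - length(common)))
  # drop residues without a CA in the common set
  first <- models[[1]]
  first <- first[akey(first) %in% common, , drop = FALSE]
  rk <- paste(first$chain, first$resno, first$ins, sep = "\r")
  hasCA <- rk %in% rk[first$atom == "CA"]
  first <- first[hasCA, , drop = FALSE]
  keys <- akey(first)

  coords <- array(NA_real_, dim = c(length(keys), 3L, length(models)))
  for (k in seq_along(models)) {
    m <- models[[k]]
    idx <- match(keys, akey(m))
    coords[, , k] <- as.matrix(m[idx, c("x", "y", "z")])
  }
  StructureBundle(first[, c("chain", "resno", "ins", "resname", "atom")], coords)
}

formatAtomName <- function(name) {
  # PDB convention: atom names of <= 3 characters start in column 14
  ifelse(nchar(name) >= 4L, sprintf("%-4s", name), sprintf(" %-3s", name))
}

pdbElement <- function(name) {
  el <- substring(sub("^[0-9']*", "", name), 1, 1)
  sprintf("%2s", el)
}

#' Write a StructureBundle as a multi-model PDB file
#'
#' @param bundle a [StructureBundle-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readBundle()]
#' @export
writeBundle <- function(bundle, path) {
  writeModels(bundle, bundle@coords, path)
}

writeModels <- function(bundle, coords, path) {
  at <- bundle@atoms
  con <- file(path, "w")
  on.exit(close(con))
  nconf <- dim(coords)[3]
  for (k in seq_len(nconf)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- coords[, , k]
    recs <- sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
                    seq_len(nrow(at)) %% 100000L, formatAtomName(at$atom),
                    at$resname, at$chain, at$resno,
                    ifelse(at$ins == "", " ", at$ins),
                    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, pdbElement(at$atom))
    writeLines(recs, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write the bundle superimposed on the selected residue ranges
#'
#' Superimposes every conformer onto the first one using the backbone atoms
#' (N, CA, C') of the residues selected in \code{result}, then writes the
#' whole bundle (all atoms, all conformers) as a multi-model PDB file.
#'
#' @param bundle a [StructureBundle-class].
#' @param result a [RangeResult-class] or [RunReport-class]; for a report the
#'   union of all domain selections is used for the fit.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSuperimposed <- function(bundle, result, path) {
  residues <- if (is(result, "RunReport")) {
    sort(unique(unlist(lapply(result@domains, function(d) d@residues))))
  } else {
    result@residues
  }
  if (length(residues) == 0L)
    stop("empty selection: no residues to superimpose on")
  sel <- backboneAtoms(bundle, residues)
  fit <- rmsdToMean(bundle, atoms = sel)
  out <- bundle@coords
  for (k in seq_len(dim(out)[3])) {
    tr <- fit$transforms[[k]]
    out[, , k] <- sweep(out[, , k] %*% tr$rotation, 2, tr$translation, "+")
  }
  writeModels(bundle, out, path)
}
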