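# Rotatable dihedral angles (phi, psi, chi1..chi5) for every conformer.
# The peptide bond dihedral omega is deliberately not computed.

# Standard IUPAC side-chain dihedral definitions.  Each chi is a quadruple of
# atom names within one residue.
CHI_ATOMS <- list(
  ARG = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "NE"), chi4 = c("CG", "CD", "NE", "CZ"),
             chi5 = c("CD", "NE", "CZ", "NH1")),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG")),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "ND1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "CE"), chi4 = c("CG", "CD", "CE", "NZ")),
  MET = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "SD"),
             chi3 = c("CB", "CG", "SD", "CE")),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1"))
)

# dihedral angle (degrees, (-180, 180]) for one quadruple of points per
# conformer; each argument is an nconf x 3 matrix
dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  crossRows <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- crossRows(b1, b2)
  n2 <- crossRows(b2, b3)
  m1 <- crossRows(b2 / sqrt(rowSums(b2^2)), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Compute all rotatable dihedral angles of a bundle
#'
#' Computes phi, psi and chi1..chi5 (standard IUPAC atom quadruples) for every
#' residue and every conformer.  The peptide bond dihedral omega is excluded.
#' An angle is emitted only if all four defining atoms exist in the bundle;
#' phi/psi additionally require the sequence neighbour to be present and
#' adjacent in author numbering, so chain-terminal angles are omitted.  For
#' residues whose name has no chi table entry (non-standard residues), chi1 is
#' still computed from N-CA-CB-CG when those atoms exist.
#'
#' @param bundle a [StructureBundle-class].
#' @param mode \code{"all"} (default) or \code{"phipsichi1"}.
#' @return A [TorsionSet-class]; possibly with zero rows (e.g. CA-only input).
#' @examples
#' b <- makeBundle(bundleSpec(regions = data.frame(n = 8, kind = "rigid",
#'                                                 sigma = 0.05),
#'                            nConf = 4, seed = 7))
#' ts <- computeTorsions(b)
#' table(ts@info$angle)
#' @export
computeTorsions <- function(bundle, mode = c("all", "phipsichi1")) {
  mode <- match.arg(mode)
  rs <- bundle@residues
  at <- bundle@atoms
  nb <- residueNeighbors(bundle)
  nconf <- nConformers(bundle)

  atomIdx <- function(res, name) {
    hit <- which(at$residue == res & at$atom == name)
    if (length(hit) == 1L) hit else NA_integer_
  }
  info <- list()
  quads <- list()
  addRec <- function(res, angle, idx) {
    if (anyNA(idx)) return()
    info[[length(info) + 1L]] <<- data.frame(
      residue = res, chain = rs$chain[res], resno = rs$resno[res],
      ins = rs$ins[res], resname = rs$resname[res], angle = angle,
      stringsAsFactors = FALSE)
    quads[[length(quads) + 1L]] <<- idx
  }
  for (res in seq_len(nrow(rs))) {
    p <- nb$prev[res]; n <- nb$nxt[res]
    if (!is.na(p))
      addRec(res, "phi", c(atomIdx(p, "C"), atomIdx(res, "N"),
                           atomIdx(res, "CA"), atomIdx(res, "C")))
    if (!is.na(n))
      addRec(res, "psi", c(atomIdx(res, "N"), atomIdx(res, "CA"),
                           atomIdx(res, "C"), atomIdx(n, "N")))
    chis <- CHI_ATOMS[[rs$resname[res]]]
    if (is.null(chis))
      chis <- list(chi1 = c("N", "CA", "CB", "CG"))
    if (mode == "phipsichi1")
      chis <- chis["chi1"]
    for (nm in names(chis)) {
      if (is.null(chis[[nm]])) next
      addRec(res, nm, vapply(chis[[nm]], atomIdx, integer(1), res = res))
    }
  }
  if (length(info) == 0L)
    return(new("TorsionSet",
               info = data.frame(residue = integer(), chain = character(),
                                 resno = integer(), ins = character(),
                                 resname = character(), angle = character()),
               values = matrix(numeric(), 0, nconf)))
  info <- do.call(rbind, info)
  values <- matrix(NA_real_, nrow(info), nconf)
  co <- bundle@coords
  for (i in seq_len(nrow(info))) {
    q <- quads[[i]]
    values[i, ] <- dihedralDeg(t(co[q[1], , ]), t(co[q[2], , ]),
                               t(co[q[3], , ]), t(co[q[4], , ]))
  }
  new("TorsionSet", info = info, values = values)
}
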