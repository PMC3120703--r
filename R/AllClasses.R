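#' @import methods
#' @importFrom stats var sd setNames
#' @importFrom utils head tail
NULL

#' StructureBundle: a multi-conformer protein structure
#'
#' Container for an ensemble of conformers (models) that share one
#' atom/residue topology, e.g. an NMR structure bundle.  Coordinates are in
#' Angstroem.  Residues are identified by author chain id, residue number and
#' insertion code; within a chain they are ordered strictly increasingly by
#' (number, insertion code).
#'
#' @slot residues data.frame with one row per residue: \code{chain},
#'   \code{resno} (integer), \code{ins} (insertion code, \code{""} if none),
#'   \code{resname}.  Row order is the sequence order used for all
#'   neighbour/gap bookkeeping.
#' @slot atoms data.frame with one row per atom: \code{chain}, \code{resno},
#'   \code{ins}, \code{resname}, \code{atom} (PDB atom name, e.g. \code{"CA"}),
#'   \code{residue} (integer index into \code{residues}).
#' @slot coords numeric array \code{n_atoms x 3 x n_conformers} (Angstroem).
#'
#' @seealso [readBundle()], [makeBundle()], [StructureBundle()]
#' @export
setClass("StructureBundle",
  representation(residues = "data.frame", atoms = "data.frame",
                 coords = "array"))

validStructureBundle <- function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_conformers array")
  if (length(d) == 3L && d[3] < 2L)
    msg <- c(msg, "insufficient conformers (need at least 2 models)")
  if (length(d) == 3L && nrow(object@atoms) != d[1])
    msg <- c(msg, "atom table and coordinate array disagree in atom count")
  at <- object@atoms
  need <- c("chain", "resno", "ins", "resname", "atom", "residue")
  if (!all(need %in% names(at)))
    msg <- c(msg, paste("atom table must have columns:", paste(need, collapse = ", ")))
  rs <- object@residues
  if (!all(c("chain", "resno", "ins", "resname") %in% names(rs)))
    msg <- c(msg, "residue table must have columns chain, resno, ins, resname")
  if (length(msg) == 0L) {
    if (anyDuplicated(paste(at$chain, at$resno, at$ins, at$atom)))
      msg <- c(msg, "duplicated (chain, residue, atom) triples")
    if (any(at$residue < 1L | at$residue > nrow(rs)))
      msg <- c(msg, "atom table references unknown residues")
    # strictly increasing residue order within each chain
    for (ch in unique(rs$chain)) {
      sub <- rs[rs$chain == ch, , drop = FALSE]
      key <- sub$resno + match(sub$ins, c("", LETTERS, letters)) / 100
      if (any(diff(key) <= 0)) {
        msg <- c(msg, sprintf("residues of chain '%s' are not strictly increasing", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("StructureBundle", validStructureBundle)

#' Construct a StructureBundle from coordinate data
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno}, \code{ins},
#'   \code{resname}, \code{atom} (one row per atom; \code{ins} may be omitted).
#' @param coords numeric array \code{n_atoms x 3 x n_conformers}, or a list of
#'   \code{n_atoms x 3} matrices (one per conformer).
#' @return A validated [StructureBundle-class] object.
#' @examples
#' at <- data.frame(chain = "A", resno = rep(1:2, each = 3),
#'                  resname = "GLY", atom = c("N", "CA", "C"))
#' xyz <- matrix(rnorm(18), 6, 3)
#' b <- StructureBundle(at, list(xyz, xyz + 1))
#' nConformers(b)
#' @export
StructureBundle <- function(atoms, coords) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(dim(coords[[1]]), length(coords)))
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  rkey <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  residues <- atoms[!duplicated(rkey), c("chain", "resno", "ins", "resname")]
  # order residues by chain (order of first appearance), then (resno, ins)
  chord <- match(residues$chain, unique(atoms$chain))
  residues <- residues[order(chord, residues$resno, match(residues$ins, c("", LETTERS, letters))), ]
  rownames(residues) <- NULL
  atoms$residue <- match(rkey, paste(residues$chain, residues$resno, residues$ins, sep = "\r"))
  new("StructureBundle", residues = residues, atoms = atoms, coords = coords)
}

#' TorsionSet: dihedral angles of a bundle across all conformers
#'
#' One row per defined rotatable dihedral angle (phi, psi, chi1..chi5; the
#' peptide bond omega is excluded), with the angle's value in every conformer.
#'
#' @slot info data.frame: \code{residue} (index into the bundle's residue
#'   table), \code{chain}, \code{resno}, \code{ins}, \code{resname},
#'   \code{angle} (\code{"phi"}, \code{"psi"}, \code{"chi1"}, ...).
#' @slot values numeric matrix, rows matching \code{info}, columns conformers;
#'   degrees in (-180, 180].
#' @seealso [computeTorsions()], [orderParameters()]
#' @export
setClass("TorsionSet", representation(info = "data.frame", values = "matrix"))

setValidity("TorsionSet", function(object) {
  if (nrow(object@info) != nrow(object@values))
    return("info and values disagree in row count")
  TRUE
})

#' ClusteringTrace: full agglomerative merge history of the core atoms
#'
#' Stage 1 holds one singleton cluster per core atom; each later stage merges
#' exactly two clusters of the previous stage, so there are as many stages as
#' core atoms.
#'
#' @slot core integer vector: residue indices whose CA atoms are the core atoms.
#' @slot labels integer matrix (stage x core atom) of cluster labels per stage.
#' @slot merges data.frame: \code{stage}, merged labels \code{a}, \code{b} and
#'   the merge cost (intra-cluster variance of the distance-variance entries).
#' @slot spread numeric: average cluster spread A_i per stage (Angstroem; NA
#'   where undefined, i.e. stage 1).
#' @slot penalty numeric: stage penalty P_i per stage (NA at stage 1).
#' @slot stage integer: the selected optimal stage (length 0 before selection).
#' @seealso [clusterCoreAtoms()], [selectClusteringStage()]
#' @export
setClass("ClusteringTrace",
  representation(core = "integer", labels = "matrix", merges = "data.frame",
                 spread = "numeric", penalty = "numeric", stage = "integer"))

#' RangeResult: refined residue ranges of one domain
#'
#' @slot ranges data.frame of inclusive ranges: \code{chain}, \code{start},
#'   \code{end} (author residue numbers), \code{startIns}, \code{endIns},
#'   \code{n} (residues in the range).
#' @slot residues integer vector of selected residue indices (bundle order).
#' @slot nResidues integer, total selected residues.
#' @slot nGaps integer, number of intra-domain gaps between ranges of one chain.
#' @slot rmsd numeric, backbone (N, CA, C') RMSD to mean coordinates of the
#'   final selection (Angstroem).
#' @slot history data.frame audit trail of the refinement (one row per
#'   iteration/removal: iteration, action, residue, r, deltaR, thresholds).
#' @seealso [refineDomain()]
#' @export
setClass("RangeResult",
  representation(ranges = "data.frame", residues = "integer",
                 nResidues = "integer", nGaps = "integer", rmsd = "numeric",
                 history = "data.frame"))

#' RangeParams: tunable parameters of the range determination
#'
#' See [rangeParams()] for defaults and meaning.
#' @slot mu integer, minimal cluster size for a domain.
#' @slot m integer, domain boundary extension (residues).
#' @slot gamma numeric, gap penalty (dimensionless, >= 0).
#' @slot delta numeric, base of the relative RMSD decrease threshold.
#' @slot deltaAbs numeric, absolute RMSD decrease threshold (Angstroem).
#' @slot g integer, minimal gap width; shorter gaps are filled.
#' @slot torsionMode character, \code{"all"} or \code{"phipsichi1"}.
#' @slot varianceNorm character, \code{"population"} or \code{"sample"}
#'   normalization of the distance variance.
#' @export
setClass("RangeParams",
  representation(mu = "integer", m = "integer", gamma = "numeric",
                 delta = "numeric", deltaAbs = "numeric", g = "integer",
                 torsionMode = "character", varianceNorm = "character"))

setValidity("RangeParams", function(object) {
  msg <- character()
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@deltaAbs <= 0) msg <- c(msg, "deltaAbs must be > 0")
  if (object@g < 1) msg <- c(msg, "g must be >= 1")
  if (object@mu < 1) msg <- c(msg, "mu must be >= 1")
  if (object@m < 0) msg <- c(msg, "m must be >= 0")
  if (!object@torsionMode %in% c("all", "phipsichi1"))
    msg <- c(msg, "torsionMode must be 'all' or 'phipsichi1'")
  if (!object@varianceNorm %in% c("population", "sample"))
    msg <- c(msg, "varianceNorm must be 'population' or 'sample'")
  if (length(msg)) msg else TRUE
})

#' RunReport: result of the full range-determination pipeline
#'
#' @slot status character: \code{"ok"}, \code{"no core atoms"} or
#'   \code{"no domains found"}.
#' @slot domains list of [RangeResult-class], one per identified domain.
#' @slot coverage numeric in [0,1]: selected residues / residues in sequence.
#' @slot nResidues integer, residues in the input sequence.
#' @slot params the [RangeParams-class] used.
#' @slot details list of diagnostics (order-parameter cutoff, core atom count,
#'   chosen clustering stage, ...).
#' @slot warnings character vector of warnings raised during the run.
#' @seealso [findResidueRanges()], [formatReport()]
#' @export
setClass("RunReport",
  representation(status = "character", domains = "list", coverage = "numeric",
                 nResidues = "integer", params = "RangeParams",
                 details = "list", warnings = "character"))

# ---- generics ----------------------------------------------------------------

#' Number of conformers in a bundle
#' @param x a [StructureBundle-class]
#' @return integer
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' Number of residues
#' @param x a [StructureBundle-class] or [RangeResult-class]
#' @return integer
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue table of a bundle
#' @param x a [StructureBundle-class]
#' @return data.frame (chain, resno, ins, resname), one row per residue
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' Atom table of a bundle
#' @param x a [StructureBundle-class]
#' @return data.frame, one row per atom
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Coordinate array of a bundle
#' @param x a [StructureBundle-class]
#' @return numeric array n_atoms x 3 x n_conformers (Angstroem)
#' @export
setGeneric("coordArray", function(x) standardGeneric("coordArray"))

#' Selected residue ranges
#' @param x a [RangeResult-class] or [RunReport-class]
#' @return data.frame of inclusive ranges
#' @export
setGeneric("resRanges", function(x) standardGeneric("resRanges"))

#' @describeIn nConformers conformer count of a bundle
#' @export
setMethod("nConformers", "StructureBundle", function(x) dim(x@coords)[3])

#' @describeIn nResidues residue count of a bundle
#' @export
setMethod("nResidues", "StructureBundle", function(x) nrow(x@residues))

#' @describeIn nResidues residues selected in a range result
#' @export
setMethod("nResidues", "RangeResult", function(x) x@nResidues)

#' @describeIn residueTable residue table of a bundle
#' @export
setMethod("residueTable", "StructureBundle", function(x) x@residues)

#' @describeIn atomTable atom table of a bundle
#' @export
setMethod("atomTable", "StructureBundle", function(x) x@atoms)

#' @describeIn coordArray coordinates of a bundle
#' @export
setMethod("coordArray", "StructureBundle", function(x) x@coords)

#' @describeIn resRanges ranges of one domain
#' @export
setMethod("resRanges", "RangeResult", function(x) x@ranges)

#' @describeIn resRanges ranges of all domains, with a \code{domain} column
#' @export
setMethod("resRanges", "RunReport", function(x) {
  if (length(x@domains) == 0L)
    return(data.frame(domain = integer(), chain = character(),
                      start = integer(), end = integer()))
  do.call(rbind, lapply(seq_along(x@domains), function(i) {
    r <- x@domains[[i]]@ranges
    cbind(domain = i, r)
  }))
})

setMethod("show", "StructureBundle", function(object) {
  cat(sprintf("StructureBundle: %d conformers, %d residues, %d atoms, %d chain(s)\n",
              nConformers(object), nrow(object@residues), nrow(object@atoms),
              length(unique(object@residues$chain))))
  ch <- split(object@residues$resno, object@residues$chain)
  for (nm in names(ch))
    cat(sprintf("  chain %s: residues %d..%d (%d)\n", nm, min(ch[[nm]]),
                max(ch[[nm]]), length(ch[[nm]])))
})

setMethod("show", "TorsionSet", function(object) {
  cat(sprintf("TorsionSet: %d dihedral angles x %d conformers\n",
              nrow(object@info), ncol(object@values)))
  print(table(object@info$angle))
})

setMethod("show", "ClusteringTrace", function(object) {
  cat(sprintf("ClusteringTrace: %d core atoms, %d stages\n",
              length(object@core), nrow(object@labels)))
  if (length(object@stage))
    cat(sprintf("  selected stage %d (%d clusters)\n", object@stage,
                length(unique(object@labels[object@stage, ]))))
})

setMethod("show", "RangeResult", function(object) {
  cat("RangeResult:", formatRanges(object), "\n")
})

setMethod("show", "RangeParams", function(object) {
  cat(sprintf(paste0("RangeParams: mu=%d m=%d gamma=%.2f delta=%.2f ",
                     "deltaAbs=%.2f g=%d torsionMode=%s varianceNorm=%s\n"),
              object@mu, object@m, object@gamma, object@delta, object@deltaAbs,
              object@g, object@torsionMode, object@varianceNorm))
})

setMethod("show", "RunReport", function(object) {
  cat(formatReport(object, format = "text"), sep = "\n")
})
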