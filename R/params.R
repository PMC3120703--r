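#' Parameters of the residue-range determination
#'
#' Returns the parameter set controlling domain identification and range
#' refinement.  The defaults are the standard single parameter set that is
#' intended to work without protein-specific adjustment.
#'
#' @param mu minimal number of core atoms a cluster needs to be considered a
#'   domain (default 8).
#' @param m number of residues by which each identified domain is extended at
#'   every range boundary before refinement, clipped at chain termini
#'   (default 3).
#' @param gamma dimensionless gap penalty weighting the RMSD decrease of a
#'   removal that opens a new gap (default 0.4).  \code{gamma = 0} forbids new
#'   gaps entirely; \code{gamma = 1} treats gap-opening removals on an equal
#'   footing with range-shortening ones.
#' @param delta base of the relative RMSD decrease threshold; the effective
#'   threshold is \code{delta + 3.0/M} where \code{M} is the current number of
#'   selected residues (default 1.2).  The inflation at small \code{M}
#'   guarantees termination.
#' @param deltaAbs minimally required absolute RMSD decrease in Angstroem
#'   (default 1.6).
#' @param g minimal gap width in residues; runs of unselected residues strictly
#'   shorter than \code{g} between selected residues of one chain are filled
#'   after convergence (default 3).
#' @param torsionMode \code{"all"} (default) computes order parameters from all
#'   rotatable dihedral angles (phi, psi, chi1..chi5, never omega);
#'   \code{"phipsichi1"} restricts to phi, psi and chi1.
#' @param varianceNorm normalization of the distance variance matrix:
#'   \code{"population"} (default, divide by the number of conformers) or
#'   \code{"sample"}.  Since every entry is rescaled by the same factor, the
#'   clustering and all downstream results are identical under either choice.
#' @return A validated [RangeParams-class] object.
#' @examples
#' rangeParams()
#' rangeParams(gamma = 0)  # never open a new gap
#' @export
rangeParams <- function(mu = 8L, m = 3L, gamma = 0.4, delta = 1.2,
                        deltaAbs = 1.6, g = 3L,
                        torsionMode = c("all", "phipsichi1"),
                        varianceNorm = c("population", "sample")) {
  new("RangeParams", mu = as.integer(mu), m = as.integer(m),
      gamma = as.numeric(gamma), delta = as.numeric(delta),
      deltaAbs = as.numeric(deltaAbs), g = as.integer(g),
      torsionMode = match.arg(torsionMode),
      varianceNorm = match.arg(varianceNorm))
}
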