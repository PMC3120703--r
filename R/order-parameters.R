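# Angular order parameters, automatic cutoff selection, and core atoms.

#' Angular order parameter of each dihedral angle
#'
#' For a torsion angle with values theta_k over the N conformers, the order
#' parameter is the length of the mean resultant of the angles treated as unit
#' vectors,
#' \deqn{S = \frac{1}{N}\left|\sum_{k=1}^{N} e^{i\theta_k}\right|
#'       = \frac{1}{N}\sqrt{\Big(\sum_k \cos\theta_k\Big)^2 +
#'                          \Big(\sum_k \sin\theta_k\Big)^2},}
#' so that 0 <= S <= 1, S = 1 for identical angles, and S = 0 for maximally
#' dispersed ones (e.g. two antipodal values).  S is invariant under adding a
#' constant to all angles (circular shift) and under rigid motions of the
#' conformers.
#'
#' @param x a [TorsionSet-class], or a numeric matrix of angles in degrees
#'   (rows = torsions, columns = conformers), or a numeric vector for a single
#'   torsion.
#' @return numeric vector of order parameters, one per torsion.
#' @examples
#' orderParameters(c(57, 57, 57))        # 1
#' orderParameters(c(0, 180))            # 0
#' orderParameters(c(0, 90, 0, 90))      # sqrt(2)/2
#' @export
orderParameters <- function(x) {
  v <- if (is(x, "TorsionSet")) x@values else x
  if (is.vector(v)) v <- matrix(v, nrow = 1)
  if (ncol(v) < 2L)
    stop("need at least 2 angle values per torsion")
  th <- v * pi / 180
  sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2)
}

#' Automatic order-parameter cutoff
#'
#' Chooses the cutoff S_cut separating well-ordered from disordered torsion
#' angles without imposing a fixed value.  The s order parameters are ranked
#' ascending (rank r_i = 1 for the smallest S_i), and the cutoff is the S_i of
#' the rank that maximizes
#' \deqn{Q_i = \frac{r_i}{s}\cdot\frac{S^{max} - S_i}{S^{max} - S^{min}},}
#' the fraction of torsion angles at or below rank r_i times the normalized
#' order-parameter headroom above S_i.  On bundles with distinct ordered and
#' disordered populations both factors are simultaneously large only at the
#' top of the disordered population, so Q has a clear maximum there --
#' regardless of which population is the larger one -- and the strict
#' condition S > S_cut retains exactly the ordered population.  Ties are
#' broken towards the smallest rank, making the choice deterministic.
#'
#' @param S numeric vector of order parameters (or a [TorsionSet-class], whose
#'   order parameters are computed first).
#' @return list with \code{cutoff} (S_cut), \code{rank} (the maximizing rank),
#'   \code{Q} (the per-rank quantity, in ascending-S order), \code{sorted}
#'   (the sorted S values), \code{order} (permutation sorting \code{S}).
#' @examples
#' S <- c(rep(0.2, 5), rep(0.9, 5)) + seq(0, 0.04, length.out = 10)
#' selectOrderCutoff(S)$cutoff
#' @export
selectOrderCutoff <- function(S) {
  if (is(S, "TorsionSet")) S <- orderParameters(S)
  s <- length(S)
  if (s < 2L)
    stop("need at least 2 order parameters")
  if (diff(range(S)) == 0)
    stop("degenerate order parameters: all values are equal, no cutoff definable")
  ord <- order(S)
  Ssort <- S[ord]
  r <- seq_len(s)
  Q <- (r / s) * (Ssort[s] - Ssort) / (Ssort[s] - Ssort[1])
  best <- which.max(Q)              # ties -> smallest rank
  list(cutoff = Ssort[best], rank = best, Q = Q, sorted = Ssort, order = ord)
}

#' Core atom determination
#'
#' The core atoms are the CA atoms of those residues that contain at least one
#' well-ordered torsion angle with order parameter strictly above the cutoff.
#'
#' @param bundle a [StructureBundle-class].
#' @param torsions the bundle's [TorsionSet-class].
#' @param cutoff the order-parameter cutoff, e.g. from [selectOrderCutoff()].
#' @param S optional precomputed order parameters matching \code{torsions}.
#' @return sorted integer vector of core residue indices.
#' @export
findCoreAtoms <- function(bundle, torsions, cutoff, S = NULL) {
  if (is.null(S)) S <- orderParameters(torsions)
  res <- sort(unique(torsions@info$residue[S > cutoff]))
  hasCA <- unique(bundle@atoms$residue[bundle@atoms$atom == "CA"])
  res <- res[res %in% hasCA]
  if (length(res) == 0L)
    stop("no core atoms: no residue has a well-ordered torsion angle and a CA atom")
  res
}
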