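# Numerical kernel: SVD superposition, RMSD to mean coordinates, and
# per-residue displacements.  Every other module calls into this file.

BACKBONE <- c("N", "CA", "C")

# indices of backbone atoms (N, CA, C') of the given residues, ordered by
# residue then atom
backboneAtoms <- function(bundle, residues) {
  at <- bundle@atoms
  hit <- at$residue %in% residues & at$atom %in% BACKBONE
  idx <- which(hit)
  idx[order(at$residue[idx], match(at$atom[idx], BACKBONE))]
}

# logical per residue: has all of N, CA, C'
completeBackbone <- function(bundle) {
  at <- bundle@atoms
  n <- nrow(bundle@residues)
  out <- rep(FALSE, n)
  bb <- at[at$atom %in% BACKBONE, ]
  cnt <- table(factor(bb$residue, levels = seq_len(n)))
  out[as.integer(names(cnt))[cnt == 3L]] <- TRUE
  out
}

# previous/next residue index along the chain, NA at termini and across
# numbering breaks (author numbering difference > 1 with no insertion codes)
residueNeighbors <- function(bundle) {
  rs <- bundle@residues
  n <- nrow(rs)
  prv <- rep(NA_integer_, n)
  nxt <- rep(NA_integer_, n)
  if (n >= 2L) {
    sameChain <- rs$chain[-1] == rs$chain[-n]
    adjacent <- sameChain &
      (rs$resno[-1] - rs$resno[-n] <= 1L | rs$ins[-1] != "" | rs$ins[-n] != "")
    prv[which(adjacent) + 1L] <- which(adjacent)
    nxt[which(adjacent)] <- which(adjacent) + 1L
  }
  list(prev = prv, nxt = nxt)
}

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Finds the proper rotation and translation that minimize the RMSD between
#' \code{moving} and \code{reference} (matched atom order), via singular value
#' decomposition of the cross-covariance matrix.  If the optimal orthogonal
#' matrix is a reflection, the sign of the smallest singular direction is
#' flipped so that the returned rotation is always proper (determinant +1).
#'
#' @param reference numeric n x 3 matrix (Angstroem).
#' @param moving numeric n x 3 matrix, same n and atom order.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   such that \code{moving \%*\% rotation + translation} best fits
#'   \code{reference}, and \code{rmsd} (Angstroem).
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' R <- diag(3)[, c(2, 1, 3)] * c(1, -1, 1)  # a rotation
#' fit <- superposePair(x, x %*% R)
#' fit$rmsd  # ~0
#' @export
superposePair <- function(reference, moving) {
  reference <- as.matrix(reference)
  moving <- as.matrix(moving)
  n <- nrow(reference)
  if (n < 3L || nrow(moving) != n)
    stop("underdetermined fit: need at least 3 matched atoms")
  cr <- colMeans(reference)
  cm <- colMeans(moving)
  X <- sweep(reference, 2, cr)
  Y <- sweep(moving, 2, cm)
  H <- crossprod(Y, X)                       # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Y %*% R
  rmsd <- sqrt(mean(rowSums((fitted - X)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

applyTransform <- function(xyz, tr) {
  sweep(xyz %*% tr$rotation, 2, tr$translation, "+")
}

#' Ensemble RMSD to the mean coordinates
#'
#' Superimposes every conformer onto the first one using the selected atoms,
#' computes the mean coordinates of the selection over conformers, and returns
#' the average over conformers of each conformer's RMSD to the mean.  For a
#' two-conformer bundle this equals half the pairwise RMSD between the two
#' structures.  The mean is not re-fit iteratively.
#'
#' @param bundle a [StructureBundle-class].
#' @param residues integer residue indices; their backbone atoms (N, CA, C')
#'   form the selection.  Ignored when \code{atoms} is given.
#' @param atoms integer atom indices forming the selection directly.
#' @return list with \code{rmsd} (the ensemble RMSD r, Angstroem),
#'   \code{mean} (n x 3 mean coordinates), \code{transforms} (per-conformer
#'   rigid transforms onto conformer 1), \code{atomDisp} (per-atom mean
#'   displacement from the mean position, Angstroem) and \code{atoms} (the
#'   selection used).
#' @seealso [meanDisplacements()], [superposePair()]
#' @export
rmsdToMean <- function(bundle, residues = NULL, atoms = NULL) {
  if (is.null(atoms)) {
    if (is.null(residues))
      stop("give either residues or atoms")
    atoms <- backboneAtoms(bundle, residues)
  }
  if (length(atoms) == 0L)
    stop("empty selection")
  nconf <- nConformers(bundle)
  ref <- bundle@coords[atoms, , 1, drop = FALSE][, , 1]
  if (length(atoms) == 1L) ref <- matrix(ref, 1L, 3L)
  fitted <- array(NA_real_, dim = c(length(atoms), 3L, nconf))
  transforms <- vector("list", nconf)
  for (k in seq_len(nconf)) {
    xyz <- matrix(bundle@coords[atoms, , k], length(atoms), 3L)
    tr <- superposePair(ref, xyz)
    transforms[[k]] <- tr
    fitted[, , k] <- applyTransform(xyz, tr)
  }
  mn <- apply(fitted, c(1, 2), mean)
  perConf <- vapply(seq_len(nconf), function(k)
    sqrt(mean(rowSums((fitted[, , k] - mn)^2))), numeric(1))
  dev <- vapply(seq_len(nconf), function(k)
    sqrt(rowSums((fitted[, , k] - mn)^2)), numeric(length(atoms)))
  atomDisp <- rowMeans(matrix(dev, nrow = length(atoms)))
  list(rmsd = mean(perConf), mean = mn, transforms = transforms,
       atomDisp = atomDisp, atoms = atoms)
}

#' Per-residue average displacement after ensemble superposition
#'
#' Displacement of a residue is the distance between an atom in a given
#' conformer and its mean position after optimal superposition of all
#' conformers onto the first, averaged over all conformers and over the
#' backbone atoms N, CA, C' of the residue.
#'
#' @param bundle a [StructureBundle-class].
#' @param residues integer residue indices defining the fitted selection.
#' @param fit optionally, a precomputed [rmsdToMean()] result for exactly this
#'   selection (avoids refitting).
#' @return named numeric vector of displacements (Angstroem), names are the
#'   residue indices.
#' @export
meanDisplacements <- function(bundle, residues, fit = NULL) {
  if (is.null(fit))
    fit <- rmsdToMean(bundle, residues = residues)
  resOf <- bundle@atoms$residue[fit$atoms]
  disp <- tapply(fit$atomDisp, resOf, mean)
  out <- as.numeric(disp)
  names(out) <- names(disp)
  out
}
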