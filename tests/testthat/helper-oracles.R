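# Independent oracles and small fixture builders used across the suite.

# Quaternion characteristic-polynomial superposition oracle (Horn's method):
# minimal RMSD between two centred point sets from the largest eigenvalue of
# the 4x4 key matrix.  Entirely independent of the package's SVD kernel.
quatRMSD <- function(X, Y) {
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  M <- crossprod(Y, X)   # sum over atoms of y_i x_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       Syy - Sxx - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       Szz - Sxx - Syy),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lambda) / nrow(X)
  sqrt(max(0, msd))
}

rotMat <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

randomRigid <- function(X) {
  R <- rotMat(rnorm(3), runif(1, 0, 2 * pi))
  sweep(X %*% R, 2, runif(3, -10, 10), "+")
}

# bundle of arbitrary point clouds: k "residues" per conformer, each carrying
# backbone atoms N, CA, C (coordinates are the rows of each matrix, whose row
# count must be a multiple of 3)
pointBundle <- function(confs) {
  n <- nrow(confs[[1]])
  stopifnot(n %% 3 == 0)
  at <- data.frame(chain = "A", resno = rep(seq_len(n / 3), each = 3),
                   resname = "GLY", atom = rep(c("N", "CA", "C"), n / 3))
  StructureBundle(at, confs)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

selectedResidues <- function(report) {
  sort(unique(unlist(lapply(report@domains, function(d) d@residues))))
}

totalGaps <- function(report) {
  sum(vapply(report@domains, function(d) d@nGaps, integer(1)))
}

# canonical fixtures (study conditions: 0.1 A core noise, uniformly random
# torsions in disordered regions, 20-conformer bundles)
helixTailsSpec <- function(seed) {
  bundleSpec(regions = data.frame(n = c(15, 40, 15),
                                  kind = c("tail", "rigid", "tail"),
                                  sigma = c(0, 0.1, 0)),
             nConf = 20, seed = seed)
}

twoDomainSpec <- function(seed) {
  bundleSpec(regions = data.frame(n = c(40, 10, 40),
                                  kind = c("rigid", "linker", "rigid"),
                                  sigma = c(0.1, 0, 0.1)),
             nConf = 20, seed = seed, domainMotion = "independent")
}

rigidSpec <- function(seed, n = 30, nConf = 10) {
  bundleSpec(regions = data.frame(n = n, kind = "rigid", sigma = 0),
             nConf = nConf, seed = seed)
}

loopSpec <- function(seed) {
  bundleSpec(regions = data.frame(n = c(20, 4, 24),
                                  kind = c("rigid", "noisy", "rigid"),
                                  sigma = c(0.1, 3, 0.1),
                                  domain = c(1, 1, 1)),
             nConf = 20, seed = seed)
}
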