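# Seeded generator of synthetic structure bundles with known
# ordered/disordered ground truth.  Backbones are built from ideal internal
# coordinates; side chains carry CB plus a chi1-defining CG atom so that the
# full rotatable-dihedral path of the pipeline is exercised.

unitv <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D bonded to C with bond length r, angle B-C-D theta (deg) and
# dihedral A-B-C-D phi (deg)
placeAtom <- function(A, B, C, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- unitv(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

randomRotationMatrix <- function(maxAngleDeg = 360) {
  axis <- stats::rnorm(3)
  rotationMatrix(axis, stats::runif(1, 0, maxAngleDeg))
}

# ideal geometry (Angstroem / degrees)
GEO <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
            bCACB = 1.53, bCBCG = 1.52,
            aNCAC = 111.0, aCACN = 116.6, aCNCA = 121.7, aCACO = 120.8,
            aNCACB = 110.5, aCACBCG = 114.0, dCNCACB = -122.6)

HELIX <- c(phi = -57, psi = -47, chi1 = -60)

#' Specification of a synthetic structure bundle
#'
#' Describes a single-chain bundle as a tiling of sequence regions.  Region
#' kinds: \code{"rigid"} and \code{"noisy"} regions share one ideal helical
#' backbone (identical torsions in every conformer) perturbed by isotropic
#' Gaussian coordinate noise of the region's \code{sigma}; \code{"tail"} and
#' \code{"linker"} regions have their backbone and chi1 torsions resampled
#' uniformly in every conformer (realistically disordered).  Rigid/noisy
#' regions form structural domains: consecutive such regions share a domain,
#' a linker starts a new one.  With \code{domainMotion = "independent"} each
#' domain additionally receives an independent random rigid rotation per
#' conformer (up to \code{maxRotation} degrees about its centroid), emulating
#' flexibly connected multi-domain proteins.
#'
#' @param regions data.frame with columns \code{n} (residues), \code{kind}
#'   (\code{"rigid"}, \code{"noisy"}, \code{"tail"}, \code{"linker"}) and
#'   optionally \code{sigma} (Angstroem, default 0) and \code{domain}
#'   (integer domain id; defaults as described above).
#' @param nConf number of conformers (default 20, typical for NMR bundles).
#' @param seed integer seed; generation is fully reproducible from it.
#' @param domainMotion \code{"shared"} (default) or \code{"independent"}.
#' @param maxRotation maximal per-domain rotation angle in degrees
#'   (default 90).
#' @param sidechains logical (default TRUE): build CB and the chi1-defining
#'   CG atom.  \code{FALSE} gives a glycine-like backbone-only chain whose
#'   only rotatable dihedrals are phi and psi.
#' @return a \code{bundleSpec} list.
#' @examples
#' bundleSpec(regions = data.frame(n = c(10, 40, 10),
#'                                 kind = c("tail", "rigid", "tail"),
#'                                 sigma = c(0, 0.1, 0)),
#'            nConf = 10, seed = 1)
#' @seealso [makeBundle()], [groundTruth()]
#' @export
bundleSpec <- function(regions, nConf = 20L, seed = 1L,
                       domainMotion = c("shared", "independent"),
                       maxRotation = 90, sidechains = TRUE) {
  domainMotion <- match.arg(domainMotion)
  regions <- as.data.frame(regions)
  stopifnot(all(c("n", "kind") %in% names(regions)),
            all(regions$kind %in% c("rigid", "noisy", "tail", "linker")),
            all(regions$n >= 1), nConf >= 2)
  if (is.null(regions$sigma)) regions$sigma <- 0
  regions$sigma[is.na(regions$sigma)] <- 0
  stopifnot(all(regions$sigma >= 0))
  if (is.null(regions$domain)) {
    dom <- rep(NA_integer_, nrow(regions))
    cur <- 1L
    open <- FALSE
    for (i in seq_len(nrow(regions))) {
      if (regions$kind[i] %in% c("rigid", "noisy")) {
        dom[i] <- cur
        open <- TRUE
      } else if (regions$kind[i] == "linker" && open) {
        cur <- cur + 1L
        open <- FALSE
      }
    }
    regions$domain <- dom
  }
  structure(list(regions = regions, nConf = as.integer(nConf),
                 seed = as.integer(seed), domainMotion = domainMotion,
                 maxRotation = maxRotation, sidechains = isTRUE(sidechains)),
            class = "bundleSpec")
}

#' Generate a synthetic structure bundle
#'
#' Builds the bundle described by a [bundleSpec()]: an idealized
#' polypeptide backbone (atoms N, CA, C', O plus CB and a chi1-defining CG)
#' assembled from internal coordinates, with per-conformer random torsions in
#' disordered regions, optional independent per-domain rigid rotations, one
#' shared random rigid motion per conformer, and isotropic Gaussian
#' coordinate noise per region.  Fully reproducible from the spec's seed; the
#' caller's random number generator state is left untouched.
#'
#' @param spec a [bundleSpec()].
#' @return a [StructureBundle-class].
#' @examples
#' b <- makeBundle(bundleSpec(regions = data.frame(n = 20, kind = "rigid",
#'                                                 sigma = 0.1),
#'                            nConf = 5, seed = 42))
#' b
#' @export
makeBundle <- function(spec) {
  stopifnot(inherits(spec, "bundleSpec"))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(spec$seed)

  reg <- spec$regions
  L <- sum(reg$n)
  regionOf <- rep(seq_len(nrow(reg)), reg$n)
  kind <- reg$kind[regionOf]
  sigma <- reg$sigma[regionOf]
  domain <- reg$domain[regionOf]
  flexible <- kind %in% c("tail", "linker")

  atomNames <- if (spec$sidechains) c("N", "CA", "C", "O", "CB", "CG")
               else c("N", "CA", "C", "O")
  napr <- length(atomNames)
  atoms <- data.frame(chain = "A", resno = rep(seq_len(L), each = napr),
                      ins = "", resname = if (spec$sidechains) "LEU" else "GLY",
                      atom = rep(atomNames, L), stringsAsFactors = FALSE)
  nat <- nrow(atoms)
  coords <- array(NA_real_, dim = c(nat, 3L, spec$nConf))
  aidx <- function(res, name) (res - 1L) * napr + match(name, atomNames)

  for (k in seq_len(spec$nConf)) {
    phi <- rep(HELIX["phi"], L)
    psi <- rep(HELIX["psi"], L)
    chi1 <- rep(HELIX["chi1"], L)
    nflex <- sum(flexible)
    if (nflex > 0L) {
      phi[flexible] <- stats::runif(nflex, -180, 180)
      psi[flexible] <- stats::runif(nflex, -180, 180)
      chi1[flexible] <- stats::runif(nflex, -180, 180)
    }
    xyz <- matrix(NA_real_, nat, 3L)
    # seed the first residue
    xyz[aidx(1L, "N"), ] <- c(0, 0, 0)
    xyz[aidx(1L, "CA"), ] <- c(GEO$bNCA, 0, 0)
    a <- GEO$aNCAC * pi / 180
    xyz[aidx(1L, "C"), ] <- xyz[aidx(1L, "CA"), ] +
      GEO$bCAC * c(-cos(a), sin(a), 0)
    for (i in seq_len(L)) {
      N <- xyz[aidx(i, "N"), ]; CA <- xyz[aidx(i, "CA"), ]
      C <- xyz[aidx(i, "C"), ]
      xyz[aidx(i, "O"), ] <- placeAtom(N, CA, C, GEO$bCO, GEO$aCACO,
                                       psi[i] + 180)
      if (spec$sidechains) {
        xyz[aidx(i, "CB"), ] <- placeAtom(C, N, CA, GEO$bCACB, GEO$aNCACB,
                                          GEO$dCNCACB)
        xyz[aidx(i, "CG"), ] <- placeAtom(N, CA, xyz[aidx(i, "CB"), ],
                                          GEO$bCBCG, GEO$aCACBCG, chi1[i])
      }
      if (i < L) {
        nextN <- placeAtom(N, CA, C, GEO$bCN, GEO$aCACN, psi[i])
        nextCA <- placeAtom(CA, C, nextN, GEO$bNCA, GEO$aCNCA, 180)
        nextC <- placeAtom(C, nextN, nextCA, GEO$bCAC, GEO$aNCAC, phi[i + 1L])
        xyz[aidx(i + 1L, "N"), ] <- nextN
        xyz[aidx(i + 1L, "CA"), ] <- nextCA
        xyz[aidx(i + 1L, "C"), ] <- nextC
      }
    }
    # independent per-domain rigid rotations
    if (spec$domainMotion == "independent") {
      for (d in unique(domain[!is.na(domain)])) {
        rows <- which(atoms$resno %in% which(!is.na(domain) & domain == d))
        R <- randomRotationMatrix(spec$maxRotation)
        ctr <- colMeans(xyz[rows, , drop = FALSE])
        xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, ctr) %*% R,
                             2, ctr, "+")
      }
    }
    # one shared rigid motion per conformer
    R <- randomRotationMatrix(360)
    xyz <- sweep(xyz %*% R, 2, stats::runif(3, -20, 20), "+")
    # regional coordinate noise
    noisy <- sigma[atoms$resno] > 0
    if (any(noisy))
      xyz[noisy, ] <- xyz[noisy, ] +
        stats::rnorm(3L * sum(noisy), sd = rep(sigma[atoms$resno][noisy], 3L))
    coords[, , k] <- xyz
  }
  StructureBundle(atoms, coords)
}

#' Ground truth of a synthetic bundle
#'
#' @param spec a [bundleSpec()].
#' @return list with \code{ordered} (residue indices of rigid/low-noise
#'   regions, sigma <= 0.5 Angstroem), \code{disordered} (the complement) and
#'   \code{domains} (list of expected per-domain ordered residue sets, one
#'   per independently moving rigid block).
#' @export
groundTruth <- function(spec) {
  stopifnot(inherits(spec, "bundleSpec"))
  reg <- spec$regions
  regionOf <- rep(seq_len(nrow(reg)), reg$n)
  kind <- reg$kind[regionOf]
  sigma <- reg$sigma[regionOf]
  domain <- reg$domain[regionOf]
  ordered <- which(kind %in% c("rigid", "noisy") & sigma <= 0.5)
  doms <- split(ordered, domain[ordered])
  list(ordered = ordered, disordered = setdiff(seq_along(kind), ordered),
       domains = unname(doms))
}
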