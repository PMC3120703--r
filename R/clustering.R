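# Distance-variance matrix, agglomerative clustering of the core atoms,
# cluster spread/penalty per stage, optimal stage selection, and domain
# extraction.

#' Distance variance matrix of the core atoms
#'
#' Entry V_ij is the variance over the N conformers of the intra-conformer
#' distance d_ijk between core atoms (CA) i and j.  The matrix is invariant
#' under rigid motions applied per conformer.  With the default population
#' normalization \eqn{V_{ij} = \frac{1}{N}\sum_k (d_{ijk} - \bar d_{ij})^2};
#' sample normalization divides by N - 1 instead.  Since that is a uniform
#' rescaling of the whole matrix, the clustering and all downstream results do
#' not depend on the choice.
#'
#' @param bundle a [StructureBundle-class].
#' @param core integer vector of core residue indices (CA atoms used).
#' @param norm \code{"population"} (default) or \code{"sample"}.
#' @return C x C symmetric matrix (Angstroem squared) with zero diagonal.
#' @export
distanceVarianceMatrix <- function(bundle, core,
                                   norm = c("population", "sample")) {
  norm <- match.arg(norm)
  if (length(core) < 2L)
    stop("need at least 2 core atoms")
  at <- bundle@atoms
  ca <- vapply(core, function(r) {
    hit <- which(at$residue == r & at$atom == "CA")
    if (length(hit) != 1L)
      stop("core residue without a unique CA atom")
    hit
  }, integer(1))
  nconf <- nConformers(bundle)
  C <- length(core)
  s1 <- matrix(0, C, C)
  s2 <- matrix(0, C, C)
  for (k in seq_len(nconf)) {
    d <- as.matrix(stats::dist(bundle@coords[ca, , k]))
    s1 <- s1 + d
    s2 <- s2 + d^2
  }
  V <- s2 / nconf - (s1 / nconf)^2
  V[V < 0] <- 0                       # numerical guard
  if (norm == "sample")
    V <- V * nconf / (nconf - 1)
  dimnames(V) <- list(core, core)
  V
}

# variance criterion for a merged cluster: the population variance of the
# V entries over all atom pairs in the cluster, or the single V value if the
# cluster has exactly two atoms
mergeCost <- function(V, members) {
  v <- V[members, members][upper.tri(diag(length(members)))]
  if (length(v) == 1L)
    return(v)
  mean(v^2) - mean(v)^2
}

#' Agglomerative clustering of the core atoms
#'
#' Ward-style hierarchical clustering on the distance-variance matrix.  At
#' stage 1 every core atom is a singleton; at each subsequent stage the two
#' clusters are merged that yield, after merging, the lowest intra-cluster
#' variance of the V entries over all atom pairs in the merged cluster (for a
#' two-atom cluster, the single V value itself).  All other clusters propagate
#' unchanged, so there are exactly as many stages as core atoms.  Equal merge
#' costs are resolved towards the pair with the lexicographically smallest
#' member indices, making the trace deterministic.
#'
#' @param V distance variance matrix from [distanceVarianceMatrix()].
#' @param core optional integer vector of core residue indices (defaults to
#'   the row names of \code{V}).
#' @return A [ClusteringTrace-class] (spread/penalty slots filled later by
#'   [selectClusteringStage()]).
#' @export
clusterCoreAtoms <- function(V, core = NULL) {
  C <- nrow(V)
  if (is.null(core))
    core <- if (!is.null(rownames(V))) as.integer(rownames(V)) else seq_len(C)
  if (C < 2L)
    stop("need at least 2 core atoms")
  labels <- matrix(NA_integer_, C, C)
  labels[1, ] <- seq_len(C)
  members <- as.list(seq_len(C))
  active <- seq_len(C)
  # cached merge costs between active clusters
  cost <- matrix(Inf, C, C)
  for (i in seq_len(C - 1L))
    for (j in seq.int(i + 1L, C))
      cost[i, j] <- V[i, j]
  merges <- data.frame(stage = integer(), a = integer(), b = integer(),
                       cost = numeric())
  lab <- seq_len(C)
  for (stage in seq.int(2L, C)) {
    sub <- cost[active, active, drop = FALSE]
    best <- min(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # tie-break: smallest (min member of a, min member of b)
    ka <- active[hits[, 1]]
    kb <- active[hits[, 2]]
    lo <- pmin(vapply(members[ka], min, integer(1)),
               vapply(members[kb], min, integer(1)))
    hi <- pmax(vapply(members[ka], min, integer(1)),
               vapply(members[kb], min, integer(1)))
    pick <- order(lo, hi)[1]
    a <- ka[pick]; b <- kb[pick]
    merges <- rbind(merges, data.frame(stage = stage, a = a, b = b, cost = best))
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    members[b] <- list(NULL)
    active <- setdiff(active, b)
    lab[lab == b] <- a
    labels[stage, ] <- lab
    cost[b, ] <- Inf; cost[, b] <- Inf
    for (o in setdiff(active, a)) {
      cst <- mergeCost(V, c(members[[a]], members[[o]]))
      cost[min(a, o), max(a, o)] <- cst
    }
  }
  new("ClusteringTrace", core = as.integer(core), labels = labels,
      merges = merges, spread = rep(NA_real_, C), penalty = rep(NA_real_, C),
      stage = integer())
}

#' Average cluster spread of one clustering stage
#'
#' \deqn{A_i = \frac{1}{c_i} \sum_j N_j\, \mathrm{RMSD}_j,}
#' where the sum runs over all clusters with more than one member, N_j is the
#' number of core atoms in cluster j, c_i is the total number of core atoms
#' from all such clusters, and RMSD_j is the ensemble RMSD to the mean
#' coordinates (backbone N, CA, C') of the residues given by the core atoms in
#' cluster j.
#'
#' @param bundle a [StructureBundle-class].
#' @param core integer vector of core residue indices.
#' @param labels integer vector of cluster labels for the core atoms (one
#'   stage's partition).
#' @param cache optional environment used to memoize RMSD_j across stages.
#' @return the average cluster spread A_i (Angstroem), or NA if no
#'   multi-member cluster exists.
#' @export
averageClusterSpread <- function(bundle, core, labels, cache = NULL) {
  sizes <- table(labels)
  multi <- names(sizes)[sizes > 1L]
  if (length(multi) == 0L)
    return(NA_real_)
  num <- 0
  den <- 0
  for (cl in multi) {
    res <- sort(core[labels == cl])
    key <- paste(res, collapse = ",")
    r <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      val <- rmsdToMean(bundle, residues = res)$rmsd
      if (!is.null(cache)) cache[[key]] <- val
      val
    }
    num <- num + length(res) * r
    den <- den + length(res)
  }
  num / den
}

#' Select the optimal clustering stage
#'
#' Computes for every stage i = 2..C the average cluster spread A_i and the
#' stage penalty
#' \deqn{P_i = \tilde A_i + n_i, \qquad
#'       \tilde A_i = 1 + (C-2)\,\frac{A_i - A^{min}}{A^{max} - A^{min}},}
#' where n_i is the number of clusters at stage i (including singletons) and
#' the spread is min-max scaled to span the same range (1 to C-1) as the
#' cluster count.  The stage with the lowest P is chosen, provided that the
#' average size of the clusters with at least \code{mu} members exceeds
#' one eighth of the total number of core atoms, rounded up to the nearest
#' integer; otherwise a new minimum is searched in the stages above, until
#' the constraint holds or the stages are exhausted ("no domains found").
#' If the spreads are all equal to within 1e-8 Angstroem (e.g. a perfectly
#' rigid bundle) the spread term is constant and P reduces to the cluster
#' count, so the final stage is selected.
#'
#' @param trace a [ClusteringTrace-class].
#' @param bundle the [StructureBundle-class] the trace was computed from.
#' @param mu minimal cluster size for a domain (default 8).
#' @return the trace with \code{spread}, \code{penalty} and the chosen
#'   \code{stage} filled in.
#' @export
selectClusteringStage <- function(trace, bundle, mu = 8L) {
  C <- length(trace@core)
  cache <- new.env(parent = emptyenv())
  A <- rep(NA_real_, C)
  for (i in seq.int(2L, C))
    A[i] <- averageClusterSpread(bundle, trace@core, trace@labels[i, ], cache)
  def <- which(!is.na(A))
  Amin <- min(A[def]); Amax <- max(A[def])
  scaled <- if (Amax - Amin <= 1e-8) {
    ifelse(is.na(A), NA_real_, 1)
  } else {
    1 + (C - 2) * (A - Amin) / (Amax - Amin)
  }
  n <- c(NA_integer_, rev(seq_len(C - 1L)))   # n_i = C - i + 1 for i >= 2
  P <- scaled + n
  lo <- 2L
  istar <- NA_integer_
  repeat {
    cand <- seq.int(lo, C)
    cand <- cand[!is.na(P[cand])]
    if (length(cand) == 0L)
      stop("no domains found: no clustering stage satisfies the cluster-size constraint")
    i <- cand[which.min(P[cand])]
    sizes <- as.integer(table(trace@labels[i, ]))
    qual <- sizes[sizes >= mu]
    if (length(qual) > 0L && mean(qual) > ceiling(C / 8)) {
      istar <- i
      break
    }
    if (i + 1L > C)
      stop("no domains found: no clustering stage satisfies the cluster-size constraint")
    lo <- i + 1L
  }
  trace@spread <- A
  trace@penalty <- P
  trace@stage <- istar
  trace
}

# contiguous runs of residue indices (with respect to chain adjacency);
# returns list of integer vectors
residueRuns <- function(residues, neighbors) {
  residues <- sort(residues)
  if (length(residues) == 0L)
    return(list())
  runs <- list()
  cur <- residues[1]
  for (r in residues[-1]) {
    lastr <- cur[length(cur)]
    if (!is.na(neighbors$nxt[lastr]) && neighbors$nxt[lastr] == r &&
        r %in% residues) {
      cur <- c(cur, r)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- r
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs
}

#' Extract extended domains from the selected clustering stage
#'
#' Each cluster at the optimal stage with at least \code{mu} core atoms is a
#' domain.  Its core residues are converted to contiguous residue ranges,
#' each range is extended by \code{m} residues at both boundaries (clipped at
#' chain termini), and overlapping extended ranges are merged.
#'
#' @param trace a [ClusteringTrace-class] with the stage selected.
#' @param bundle the [StructureBundle-class].
#' @param mu minimal cluster size (default 8).
#' @param m boundary extension in residues (default 3).
#' @return list of domains, each a list with \code{core} (core residue
#'   indices) and \code{residues} (extended residue indices); ordered by first
#'   residue.  Empty domains never occur; zero qualifying clusters raise
#'   "no domains found".
#' @export
extractDomains <- function(trace, bundle, mu = 8L, m = 3L) {
  if (length(trace@stage) == 0L)
    stop("clustering stage not selected yet")
  nb <- residueNeighbors(bundle)
  labels <- trace@labels[trace@stage, ]
  doms <- list()
  for (cl in unique(labels)) {
    core <- sort(trace@core[labels == cl])
    if (length(core) < mu) next
    ext <- integer()
    for (run in residueRuns(core, nb)) {
      lo <- run[1]; hi <- run[length(run)]
      for (i in seq_len(m)) {
        if (!is.na(nb$prev[lo])) lo <- nb$prev[lo]
        if (!is.na(nb$nxt[hi])) hi <- nb$nxt[hi]
      }
      ext <- union(ext, seq.int(lo, hi))
    }
    doms[[length(doms) + 1L]] <- list(core = core, residues = sort(ext))
  }
  if (length(doms) == 0L)
    stop("no domains found: no cluster at the optimal stage has at least mu members")
  doms[order(vapply(doms, function(d) d$residues[1], integer(1)))]
}
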