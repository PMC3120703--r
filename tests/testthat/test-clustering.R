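# Distance-variance matrix, clustering, stage selection, domain extraction.

test_that("distance variance: hand-computed two-conformer case and both norms", {
  # two residues whose CA-CA distance is 3 A in conformer 1, 5 A in conformer 2
  at <- data.frame(chain = "A", resno = rep(1:2, each = 2), resname = "GLY",
                   atom = rep(c("N", "CA"), 2))
  c1 <- rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 1, 0), c(3, 0, 0))
  c2 <- rbind(c(-1, 0, 0), c(0, 0, 0), c(4, 1, 0), c(5, 0, 0))
  b <- StructureBundle(at, list(c1, c2))
  V <- distanceVarianceMatrix(b, 1:2)                       # population
  expect_equal(V[1, 2], 1.0)                                # var of {3,5}
  Vs <- distanceVarianceMatrix(b, 1:2, norm = "sample")
  expect_equal(Vs[1, 2], 2.0)
  expect_equal(diag(V), c(0, 0), ignore_attr = TRUE)
})

test_that("variance matrix is rigid-motion invariant and vanishes for rigid bundles", {
  set.seed(61)
  spec <- rigidSpec(61, n = 10, nConf = 5)
  b <- makeBundle(spec)
  V <- distanceVarianceMatrix(b, 1:10)
  expect_lt(max(V), 1e-10)

  bn <- makeBundle(bundleSpec(regions = data.frame(n = 10, kind = "noisy",
                                                   sigma = 0.5),
                              nConf = 5, seed = 62))
  V1 <- distanceVarianceMatrix(bn, 1:10)
  co <- coordArray(bn)
  for (k in 1:5) co[, , k] <- randomRigid(co[, , k])
  at <- atomTable(bn)
  b2 <- StructureBundle(at[, c("chain", "resno", "ins", "resname", "atom")], co)
  V2 <- distanceVarianceMatrix(b2, 1:10)
  expect_equal(V1, V2, tolerance = 1e-9)
})

test_that("clustering merges block-structured variance matrices block-first", {
  # 4 atoms: pairs {1,2} and {3,4} rigid, large cross-block variance
  V <- matrix(10, 4, 4) + matrix(rnorm(16, 0, 0.01), 4, 4)
  V <- (V + t(V)) / 2
  V[1, 2] <- V[2, 1] <- 0.01
  V[3, 4] <- V[4, 3] <- 0.02
  diag(V) <- 0
  tr <- clusterCoreAtoms(V, core = 1:4)
  expect_equal(nrow(tr@labels), 4L)          # as many stages as core atoms
  expect_equal(tr@merges$stage, 2:4)
  firstTwo <- tr@merges[1:2, c("a", "b")]
  expect_setequal(paste(firstTwo$a, firstTwo$b), c("1 2", "3 4"))
  # stage 3 has the two blocks as clusters
  expect_equal(length(unique(tr@labels[3, ])), 2L)
  expect_equal(tr@labels[3, 1], tr@labels[3, 2])
  expect_equal(tr@labels[3, 3], tr@labels[3, 4])
})

test_that("each merge minimizes the intra-cluster V variance (exhaustive oracle)", {
  set.seed(63)
  n <- 9
  V <- matrix(runif(n * n, 0, 5), n, n); V <- (V + t(V)) / 2; diag(V) <- 0
  tr <- clusterCoreAtoms(V, core = seq_len(n))
  costOf <- function(members) {
    v <- V[members, members][upper.tri(diag(length(members)))]
    if (length(v) == 1) v else mean(v^2) - mean(v)^2
  }
  labels <- seq_len(n)
  for (st in 2:n) {
    cl <- unique(labels)
    best <- Inf
    for (i in seq_along(cl)) for (j in seq_len(i - 1)) {
      m <- which(labels %in% c(cl[i], cl[j]))
      best <- min(best, costOf(m))
    }
    expect_equal(tr@merges$cost[st - 1], best, tolerance = 1e-12)
    labels[labels == tr@merges$b[st - 1]] <- tr@merges$a[st - 1]
    expect_equal(length(unique(tr@labels[st, ])), length(unique(labels)))
  }
})

test_that("average cluster spread matches direct evaluations", {
  set.seed(64)
  b <- makeBundle(bundleSpec(regions = data.frame(n = 10, kind = "noisy",
                                                  sigma = 0.3),
                             nConf = 6, seed = 64))
  # single cluster of all atoms: A equals the plain RMSD to mean
  A <- averageClusterSpread(b, core = 1:10, labels = rep(1L, 10))
  expect_equal(A, rmsdToMean(b, residues = 1:10)$rmsd, tolerance = 1e-12)

  # two clusters: size-weighted mean of the cluster RMSDs
  labels <- rep(c(1L, 2L), c(4, 6))
  r1 <- rmsdToMean(b, residues = 1:4)$rmsd
  r2 <- rmsdToMean(b, residues = 5:10)$rmsd
  expect_equal(averageClusterSpread(b, 1:10, labels),
               (4 * r1 + 6 * r2) / 10, tolerance = 1e-12)

  # singletons do not contribute
  labels2 <- c(1L, 1L, 1L, 1L, 2:7)
  expect_equal(averageClusterSpread(b, 1:10, labels2), r1, tolerance = 1e-12)

  # rigid pair among singletons: spread ~ 0
  br <- makeBundle(rigidSpec(65, n = 10, nConf = 4))
  expect_lt(averageClusterSpread(br, 1:10, labels2), 1e-6)
})

test_that("stage selection obeys the penalty minimum and the size constraint", {
  b <- makeBundle(twoDomainSpec(66))
  ts <- computeTorsions(b)
  S <- orderParameters(ts)
  core <- findCoreAtoms(b, ts, selectOrderCutoff(S)$cutoff, S = S)
  V <- distanceVarianceMatrix(b, core)
  tr <- selectClusteringStage(clusterCoreAtoms(V, core), b, mu = 8)
  C <- length(core)
  # independent re-scan with the same constraint loop
  lo <- 2L
  repeat {
    cand <- lo:C
    i <- cand[which.min(tr@penalty[cand])]
    sizes <- as.integer(table(tr@labels[i, ]))
    qual <- sizes[sizes >= 8]
    if (length(qual) && mean(qual) > ceiling(C / 8)) break
    lo <- i + 1L
  }
  expect_equal(tr@stage, i)
  # the two blocks appear as the two large clusters at the chosen stage
  sizes <- sort(as.integer(table(tr@labels[tr@stage, ])), decreasing = TRUE)
  expect_gte(sizes[2], 30)
})

test_that("stage-size constraint arithmetics follow the one-eighth rule", {
  # C = 40 core atoms, qualifying cluster sizes {12} vs mu: 12 > ceil(40/8)
  expect_true(mean(c(12)) > ceiling(40 / 8))
  # a stage whose only clusters are below mu has no qualifying clusters:
  # construct a two-stage trace where the P-minimum stage fails and the
  # search accepts a later stage
  b <- makeBundle(rigidSpec(67, n = 12, nConf = 4))
  V <- distanceVarianceMatrix(b, 1:12)
  tr <- clusterCoreAtoms(V, 1:12)
  sel <- selectClusteringStage(tr, b, mu = 8)
  sizes <- as.integer(table(sel@labels[sel@stage, ]))
  expect_true(any(sizes >= 8))
})

test_that("clustering and results are identical under both variance norms", {
  spec <- helixTailsSpec(68)
  b <- makeBundle(spec)
  r1 <- findResidueRanges(b, rangeParams(varianceNorm = "population"))
  r2 <- findResidueRanges(b, rangeParams(varianceNorm = "sample"))
  expect_identical(lapply(r1@domains, function(d) d@residues),
                   lapply(r2@domains, function(d) d@residues))
})

test_that("domain extraction extends boundaries and enforces mu", {
  b <- makeBundle(rigidSpec(69, n = 60, nConf = 3))
  mkTrace <- function(core, labels) {
    lab <- matrix(NA_integer_, length(core), length(core))
    lab[length(core), ] <- labels
    new("ClusteringTrace", core = as.integer(core), labels = lab,
        merges = data.frame(), spread = numeric(), penalty = numeric(),
        stage = length(core))
  }
  # one cluster covering residues 20..50, extended by m = 3 -> 17..53
  tr <- mkTrace(20:50, rep(1L, 31))
  doms <- extractDomains(tr, b, mu = 8, m = 3)
  expect_length(doms, 1L)
  expect_equal(doms[[1]]$residues, 17:53)
  # extension clips at chain termini
  tr2 <- mkTrace(1:10, rep(1L, 10))
  expect_equal(extractDomains(tr2, b, mu = 8, m = 3)[[1]]$residues, 1:13)
  # a 7-member cluster is not a domain when mu = 8
  tr3 <- mkTrace(c(20:26, 40:50), rep(c(1L, 2L), c(7, 11)))
  doms3 <- extractDomains(tr3, b, mu = 8, m = 3)
  expect_length(doms3, 1L)
  expect_equal(doms3[[1]]$core, 40:50)
  tr4 <- mkTrace(20:26, rep(1L, 7))
  expect_error(extractDomains(tr4, b, mu = 8, m = 3), "no domains found")
})
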