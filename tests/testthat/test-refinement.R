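# Iterative gap-penalized residue removal.

test_that("isolated residues are removed, including lone terminal ones", {
  b <- makeBundle(rigidSpec(71, n = 20, nConf = 3))
  nb <- EnsembleRange:::residueNeighbors(b)
  expect_equal(EnsembleRange:::removeIsolated(c(5L, 7:20), nb), 7:20)
  expect_equal(EnsembleRange:::removeIsolated(c(1L, 3:20), nb), 3:20)
  expect_equal(EnsembleRange:::removeIsolated(5:15, nb), 5:15)
  expect_equal(EnsembleRange:::removeIsolated(c(1L, 5L, 10L), nb), integer())
})

test_that("gap-opening status: interior residues open gaps, endpoints do not", {
  b <- makeBundle(rigidSpec(72, n = 20, nConf = 3))
  nb <- EnsembleRange:::residueNeighbors(b)
  opens <- EnsembleRange:::gapOpening(1:20, nb)
  expect_false(opens["1"]); expect_false(opens["20"])
  expect_true(all(opens[as.character(2:19)]))
  # singleton runs never open a gap
  opens2 <- EnsembleRange:::gapOpening(c(1:5, 10L), nb)
  expect_false(opens2["10"])
})

test_that("removal decision implements both thresholds as a conjunction", {
  # hand evaluation: thresholds 1.6*3/150 = 0.032 and (1.2+3/50)*3/150 = 0.0252
  expect_true(removalDecision(0.5, r = 2.0, nResAtoms = 3, nSelAtoms = 150,
                              M = 50, delta = 1.2, deltaAbs = 1.6))
  expect_false(removalDecision(0, r = 2.0, 3, 150, 50))
  # just below the absolute threshold while the relative test passes (r small)
  expect_false(removalDecision(0.0319, r = 0.5, 3, 150, 50))
  expect_true(removalDecision(0.033, r = 0.5, 3, 150, 50))
  # absolute passing but relative failing also rejects (conjunction)
  expect_false(removalDecision(0.033, r = 2.0, 3, 150, 50))
  # relative test failing alone also rejects
  expect_false(removalDecision(0.04, r = 2.0, 3, 150, M = 3, delta = 1.2))
  # r = 0 rejects
  expect_false(removalDecision(0.5, r = 0, 3, 150, 50))
})

test_that("small gaps are filled strictly below g and never across chain breaks", {
  b <- makeBundle(rigidSpec(73, n = 20, nConf = 3))
  nb <- EnsembleRange:::residueNeighbors(b)
  selectable <- rep(TRUE, 20)
  expect_equal(EnsembleRange:::fillGaps(c(1:10, 13:20), 3, nb, selectable), 1:20)
  expect_equal(EnsembleRange:::fillGaps(c(1:10, 14:20), 3, nb, selectable),
               c(1:10, 14:20))
  # two-chain bundle: the inter-chain "gap" is never filled
  at <- atomTable(b)
  at$chain <- rep(c("A", "B"), c(sum(at$resno <= 10), sum(at$resno > 10)))
  at$resno[at$chain == "B"] <- at$resno[at$chain == "B"] - 10L
  b2 <- StructureBundle(at[, c("chain", "resno", "ins", "resname", "atom")],
                        coordArray(b))
  nb2 <- EnsembleRange:::residueNeighbors(b2)
  expect_equal(EnsembleRange:::fillGaps(c(9:10, 11:12), 5, nb2, rep(TRUE, 20)),
               c(9:10, 11:12))
})

test_that("a rigid domain is left untouched with a single contiguous range", {
  b <- makeBundle(rigidSpec(74, n = 25, nConf = 5))
  res <- refineDomain(b, 1:25, rangeParams())
  expect_equal(res@residues, 1:25)
  expect_equal(nrow(res@ranges), 1L)
  expect_equal(res@nGaps, 0L)
  expect_lt(res@rmsd, 1e-6)
  expect_false(any(grepl("removed", res@history$action)))
})

test_that("strongly disordered terminal residues are stripped", {
  # 60-residue domain whose last 10 residues carry 5 A noise
  spec <- bundleSpec(regions = data.frame(n = c(50, 10),
                                          kind = c("rigid", "noisy"),
                                          sigma = c(0.1, 5), domain = c(1, 1)),
                     nConf = 10, seed = 75)
  b <- makeBundle(spec)
  res <- refineDomain(b, 1:60, rangeParams())
  removedNoisy <- setdiff(51:60, res@residues)
  expect_gte(length(removedNoisy), 8)
  expect_true(all(1:45 %in% res@residues))
})

test_that("gamma = 0 never opens a new gap; larger gamma opens at least as many", {
  gaps <- vapply(c(0, 0.4, 1), function(g) {
    rep <- findResidueRanges(makeBundle(loopSpec(76)), rangeParams(gamma = g))
    totalGaps(rep)
  }, integer(1))
  expect_equal(gaps[1], 0L)
  expect_lte(gaps[2], gaps[3])
  expect_gte(gaps[2], 1L)   # the default does excise the disordered loop
})

test_that("refinement terminates within the residue budget and r never rises", {
  for (spec in list(helixTailsSpec(77), twoDomainSpec(78))) {
    b <- makeBundle(spec)
    rep <- findResidueRanges(b)
    for (d in rep@domains) {
      h <- d@history
      # every iteration except the last removes at least one residue, so the
      # iteration count is bounded by the removal events (i.e. by the
      # initial residue count)
      nRemovals <- sum(h$action %in% c("isolated") | grepl("removed", h$action))
      expect_lte(max(h$iteration), nRemovals + 2L)
      # r never increases across an accepted removal: the next iteration's
      # RMSD is at most the RMSD at the iteration of the removal
      for (i in which(grepl("removed", h$action))) {
        nxt <- h$r[h$iteration == h$iteration[i] + 1L]
        if (length(nxt))
          expect_lte(nxt[1], h$r[i] + 1e-9)
      }
    }
  }
})
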