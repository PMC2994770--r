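test_that("configuration is validated and the taxonomy is balanced", {
  cfg <- simulationConfig()
  expect_s3_class(cfg, "simulationConfig")
  expect_error(simulationConfig(intraDepth = 0.3, interDepth = 0.2),
               "smaller")
  expect_error(simulationConfig(seqLength = 100), "seqLength")
  expect_error(simulationConfig(posRateMultipliers = c(1, -1, 1)),
               "positive")
  expect_error(simulationConfig(heteroplasmyRate = 0.5), "0.01")

  bundle <- simulateTaxonomy(cfg)
  tab <- bundle$taxonomy@table
  expect_equal(nrow(tab), 48L)                       # 2x2x2x3 species x2
  expect_equal(length(unique(tab$species)), 24L)
  expect_equal(length(unique(tab$family)), 8L)
  expect_equal(length(unique(tab$order)), 4L)
  expect_equal(length(unique(tab$superorder)), 2L)
  # determinism
  bundle2 <- simulateTaxonomy(cfg)
  expect_identical(ape::write.tree(bundle$tree), ape::write.tree(bundle2$tree))
})

test_that("true distances are additive on the generating tree and ranked", {
  cfg <- simulationConfig()
  bundle <- simulateTaxonomy(cfg)
  d <- bundle$trueDistances
  co <- ape::cophenetic.phylo(bundle$tree)[rownames(d), colnames(d)]
  expect_equal(d, co, tolerance = 1e-9)
  tab <- bundle$taxonomy@table
  # same species < same family < same order < same superorder < across
  dd <- function(i, j) d[tab$sample_id[i], tab$sample_id[j]]
  expect_equal(dd(1, 2), cfg$intraDepth, tolerance = 1e-9)
  expect_equal(dd(1, 3), cfg$interDepth, tolerance = 1e-9)   # same family
  expect_gt(dd(1, 7), dd(1, 3))     # different family, same order
  expect_gt(dd(1, 13), dd(1, 7))    # different order, same superorder
  expect_gt(dd(1, 25), dd(1, 13))   # different superorder
})

test_that("zero branch lengths copy the root sequence everywhere", {
  cfg <- simulationConfig(intraDepth = 0, interDepth = 1e-9,
                          heteroplasmyRate = 0, seqLength = 300L)
  # shrink all depths to zero via a custom bundle
  bundle <- simulateTaxonomy(cfg)
  bundle$tree$edge.length[] <- 0
  aln <- evolveAlignment(bundle)
  s <- as.character(aln@seqs)
  expect_true(all(s == s[1]))
})

test_that("K2P estimates recover the simulated divergence", {
  # two-leaf tree, total path 0.2, uniform position rates
  cfg <- simulationConfig(nSuperorders = 1L, ordersPerSuperorder = 1L,
                          familiesPerOrder = 1L, speciesPerFamily = 1L,
                          samplesPerSpecies = 2L, seqLength = 9999L,
                          intraDepth = 0.2, interDepth = 0.25,
                          posRateMultipliers = c(1, 1, 1),
                          heteroplasmyRate = 0)
  bundle <- simulateTaxonomy(cfg)
  ests <- vapply(1:60, function(seed) {
    aln <- evolveAlignment(bundle, seed = seed)
    s <- as.character(aln@seqs)
    k2pDistance(s[1], s[2])
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.2), 3 * se + 1e-4)
  # relative bias under 2%
  expect_lt(abs(mean(ests) - 0.2) / 0.2, 0.02)
})

test_that("codon-position rate multipliers reproduce the 3rd>1st>2nd order", {
  cfg <- simulationConfig(seqLength = 3000L, heteroplasmyRate = 0,
                          posRateMultipliers = c(1, 0.2, 5) / mean(c(1, 0.2, 5)))
  sim <- simulateLocus(cfg)
  means <- vapply(c("pos1", "pos2", "pos3"), function(sub)
    distanceSummary(pairwiseMatrix(sim$alignment, "k2p", sub))$mean,
    numeric(1))
  expect_gt(means[["pos3"]], means[["pos1"]])
  expect_gt(means[["pos1"]], means[["pos2"]])
})

test_that("heteroplasmy injection is bounded, deterministic and visible to
           the conservation rule", {
  cfg <- simulationConfig(seqLength = 300L, heteroplasmyRate = 0)
  sim <- simulateLocus(cfg)
  expect_equal(sim$nHeteroplasmic, 0L)
  h1 <- injectHeteroplasmy(sim$alignment, 0.005, seed = 2L)
  h2 <- injectHeteroplasmy(sim$alignment, 0.005, seed = 2L)
  expect_identical(as.character(h1@seqs), as.character(h2@seqs))
  expect_gt(attr(h1, "nInjected"), 0L)
  expect_equal(heteroplasmyCount(h1), attr(h1, "nInjected"))
  expect_error(injectHeteroplasmy(sim$alignment, 0.5, seed = 1L), "rate")
  expect_identical(
    as.character(injectHeteroplasmy(sim$alignment, 0, seed = 1L)@seqs),
    as.character(sim$alignment@seqs))

  # the worked heteroplasmy pattern: 1 cell A -> R among 100 sequences
  col <- c(rep("A", 99), "R")
  f <- siteFrequencies(col)
  expect_equal(as.numeric(f), c(0.99, 0, 0, 0))
})

test_that("a well-separated simulation yields a clean barcoding gap and a
           fully congruent NJ tree", {
  sim <- simulateLocus(simulationConfig(seed = 7L))
  k2p <- pairwiseMatrix(sim$alignment, "k2p")
  pairs <- labelPairs(k2p, sim$taxonomy)
  g <- gapScan(pairs)
  expect_lt(g$maxIntra, 1)
  expect_gt(g$minInter, 3)
  for (t in c(1.5, 2.0, 2.5)) {
    met <- thresholdMetrics(contingencyTable(pairs, t))
    expect_equal(unname(met[c("fpRate", "fnRate")]), c(0, 0))
  }
  tree <- njTree(k2p)
  cong <- congruenceAcrossRanks(tree, sim$taxonomy)
  expect_true(all(cong$overallPercent == 100))
})

test_that("NJ on true distances recovers the topology; estimation error
           shrinks with sequence length", {
  skip_if_not_installed("phangorn")
  cfg <- simulationConfig(speciesPerFamily = 2L)  # binary generating tree
  bundle <- simulateTaxonomy(cfg)
  exact <- njTree(bundle$trueDistances)
  expect_equal(as.numeric(phangorn::RF.dist(exact, ape::unroot(bundle$tree))),
               0)
  rf <- vapply(c(300L, 1200L, 4800L), function(L) {
    cfgL <- simulationConfig(speciesPerFamily = 2L, seqLength = L,
                             heteroplasmyRate = 0, seed = 11L)
    sim <- simulateLocus(cfgL)
    tr <- njTree(pairwiseMatrix(sim$alignment, "k2p"))
    as.numeric(phangorn::RF.dist(tr, ape::unroot(sim$truth$tree)))
  }, numeric(1))
  expect_true(all(diff(rf) <= 0))    # monotone improvement (fixed seeds)
  expect_equal(rf[3], 0)
})
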