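# Helper: a labelled-pairs frame straight from distances + flags.
pairsFrom <- function(dist, same) {
  data.frame(id1 = paste0("x", seq_along(dist)),
             id2 = paste0("y", seq_along(dist)),
             distance = dist, sameSpecies = same)
}

test_that("pair labelling collapses subspecies to one species", {
  aln <- alnFromStrings(U1 = "ACGTACGTAC", U2 = "ACGAACGTAC",
                        H1 = "ACGTACTTAC")
  tax <- taxFrom(c("U1", "U2", "H1"),
                 species = c("Ursus thibetanus", "Ursus thibetanus",
                             "Homo sapiens"),
                 subspecies = c("Ursus thibetanus ussuricus", "", ""))
  dm <- pairwiseMatrix(aln, "k2p")
  pairs <- labelPairs(dm, tax)
  expect_equal(nrow(pairs), 3L)
  expect_true(pairs$sameSpecies[pairs$id1 == "U1" & pairs$id2 == "U2"])
  expect_false(any(pairs$sameSpecies[pairs$id2 == "H1"]))
  # distances reported on the x100 scale
  expect_equal(pairs$distance[pairs$id1 == "U1" & pairs$id2 == "U2"],
               distanceValues(dm, x100 = TRUE)["U1", "U2"])
  # unresolvable id errors
  badTax <- taxFrom(c("U1", "U2"), species = c("a", "b"))
  expect_error(labelPairs(dm, badTax), "not in taxonomy")
})

test_that("contingency cells partition pairs with a strict threshold", {
  pairs <- pairsFrom(c(runif(10, 0, 1.4), runif(20, 2.6, 30)),
                     c(rep(TRUE, 10), rep(FALSE, 20)))
  ct <- contingencyTable(pairs, 1.5)
  expect_equal(c(ct@nAB, ct@naB, ct@nAb, ct@nab), c(10, 0, 0, 20))
  m <- contingencyMarginals(ct)
  expect_equal(unname(m["n"]), 30)
  expect_equal(unname(m["nA"]), unname(ct@nAB + ct@nAb))

  # a pair exactly at the threshold is negative under the strict rule
  at <- pairsFrom(c(1.5, 1.0), c(TRUE, TRUE))
  expect_equal(contingencyTable(at, 1.5)@nAb, 1)
  expect_equal(contingencyTable(at, 1.5, strict = FALSE)@nAb, 0)

  # the four cells always sum to the pair count
  set.seed(8)
  for (i in 1:20) {
    p <- pairsFrom(runif(50, 0, 5), sample(c(TRUE, FALSE), 50, TRUE))
    t <- runif(1, 0, 5)
    ct <- contingencyTable(p, t)
    expect_equal(unname(contingencyMarginals(ct)["n"]), 50)
    mm <- contingencyMarginals(ct)
    expect_equal(unname(mm["nA"] + mm["na"]), unname(mm["nB"] + mm["nb"]))
  }
})

test_that("metrics satisfy their complementary identities exactly", {
  set.seed(14)
  for (i in 1:20) {
    ct <- contingencyFromCounts(nAB = sample(0:50, 1), naB = sample(0:50, 1),
                                nAb = sample(1:50, 1), nab = sample(1:50, 1))
    met <- thresholdMetrics(ct)
    expect_equal(unname(met["fpRate"] + met["specificity"]), 1)
    expect_equal(unname(met["fnRate"] + met["sensitivity"]), 1)
  }
  perfect <- contingencyFromCounts(nAB = 10, naB = 0, nAb = 0, nab = 20)
  expect_equal(unname(thresholdMetrics(perfect)), rep(c(0, 1), c(2, 4)))
  # zero denominators are undefined markers, not errors
  degenerate <- contingencyFromCounts(nAB = 0, naB = 0, nAb = 0, nab = 5)
  expect_true(is.na(thresholdMetrics(degenerate)["sensitivity"]))
})

test_that("published-style count cells reconstruct derived metrics", {
  # counts given as (nB, nb, naB, nAb), the form threshold tables print
  ct <- contingencyFromCounts(naB = 90, nAb = 0, nB = 456056, nb = 445097)
  expect_equal(ct@nAB, 455966)
  expect_equal(ct@nab, 445097)
  met <- thresholdMetrics(ct)
  expect_equal(unname(met["fpRate"]), 90 / 445187, tolerance = 1e-12)
  expect_equal(unname(met["ppv"]), 455966 / 456056, tolerance = 1e-12)
})

test_that("gap scan locates the empty interval between classes", {
  pairs <- pairsFrom(c(runif(15, 0, 1), runif(30, 3, 30)),
                     c(rep(TRUE, 15), rep(FALSE, 30)))
  g <- gapScan(pairs)
  expect_equal(g$gapInterval, c(g$maxIntra, g$minInter))
  expect_true(g$maxIntra < 1 && g$minInter > 3)
  expect_equal(g$thresholdsInGap, c(1.5, 2.0, 2.5))
  expect_equal(sum(g$histogram$intra), 15)
  expect_equal(sum(g$histogram$inter), 30)
  # overlapping classes: no gap
  ov <- pairsFrom(c(1, 2, 3, 1.5, 2.5), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_null(gapScan(ov)$gapInterval)
  # single same-species pair
  single <- pairsFrom(c(1.16, 2.6, 5), c(TRUE, FALSE, FALSE))
  expect_equal(gapScan(single)$gapInterval, c(1.16, 2.6))
  # any threshold inside a true gap classifies perfectly
  for (t in c(1.2, 2, 2.9)) {
    met <- thresholdMetrics(contingencyTable(pairs, t))
    expect_equal(unname(met[c("fpRate", "fnRate")]), c(0, 0))
  }
})

test_that("ROC/AUC equals the brute-force U-statistic with ties at half", {
  sep <- pairsFrom(c(runif(10, 0, 1), runif(10, 2, 3)),
                   c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(rocCurve(sep)$auc, 1)
  set.seed(23)
  for (i in 1:15) {
    nA <- sample(5:60, 1); na <- sample(5:60, 1)
    # coarse grid forces ties
    d <- c(sample(seq(0, 5, by = 0.5), nA, TRUE),
           sample(seq(0, 5, by = 0.5), na, TRUE))
    p <- pairsFrom(d, rep(c(TRUE, FALSE), c(nA, na)))
    r <- rocCurve(p)
    expect_equal(r$auc, bruteAUC(d[1:nA], d[-(1:nA)]), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    # rank statistic: invariant under strictly increasing transforms
    p2 <- p; p2$distance <- exp(p$distance)
    expect_equal(rocCurve(p2)$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(rocCurve(pairsFrom(c(1, 2), c(TRUE, TRUE))), "both")
})

test_that("random labels give chance-level AUC within 3 standard errors", {
  set.seed(99)
  d <- rgamma(400, shape = 2, rate = 1)
  p <- pairsFrom(d, sample(rep(c(TRUE, FALSE), each = 200)))
  r <- rocCurve(p)
  expect_lt(abs(r$auc - 0.5), 3 * r$aucSE)
})

test_that("AUC standard error agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  d <- c(runif(40, 0, 2.5), runif(60, 1.5, 6))
  p <- pairsFrom(d, rep(c(TRUE, FALSE), c(40, 60)))
  r <- rocCurve(p)
  ref <- pROC::roc(response = !p$sameSpecies, predictor = p$distance,
                   quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("duplicate sequences are removed by exact string identity", {
  aln <- alnFromStrings(a = "ACGT", b = "ACGT", c = "ACGA")
  expect_message(dd <- deduplicateSequences(aln), "1 duplicate")
  expect_equal(sampleIds(dd), c("a", "c"))
  expect_identical(deduplicateSequences(dd), dd)
})
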