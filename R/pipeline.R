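#' @include conservation.R distances.R discrimination.R phylogeny.R
NULL

#' Run the full two-locus comparison pipeline
#'
#' Applies the identical analysis chain to each locus — conservation
#' profiling, the distance suite with bootstrap standard errors, threshold
#' discrimination with contingency metrics and ROC, neighbor-joining tree
#' construction and taxonomy congruence — and returns the per-locus reports
#' side by side. Deterministic given `seed`. Loci with fewer than 3
#' sequences skip tree construction and congruence with a warning.
#'
#' @param alignments Named list of [GeneAlignment-class] objects, one per
#'   locus (at least one; two for a paired comparison).
#' @param taxonomy A [TaxonomyTable-class] resolving every sample id.
#' @param thresholds K2P (x100) thresholds (defaults 1.5 / 2.0 / 2.5).
#' @param windows Sliding-window sizes for conservation (101 / 401 / 601).
#' @param bootstrapReplicates Bootstrap replicates for distance standard
#'   errors (default 1000).
#' @param seed Integer seed governing all bootstrap resampling.
#' @param congruenceRanks Ranks scored against the NJ tree.
#' @return List of class `locusComparison`: `loci` (named list of per-locus
#'   reports), `thresholds`, `seed`, `schemaVersion`.
#' @export
runLocusComparison <- function(alignments, taxonomy,
                               thresholds = c(1.5, 2.0, 2.5),
                               windows = c(101L, 401L, 601L),
                               bootstrapReplicates = 1000L, seed = 1L,
                               congruenceRanks = c("superorder", "order",
                                                   "family", "genus")) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)), is(taxonomy, "TaxonomyTable"))
  reports <- lapply(names(alignments), function(locus) {
    runSingleLocus(locus, alignments[[locus]], taxonomy, thresholds,
                   windows, bootstrapReplicates, seed, congruenceRanks)
  })
  names(reports) <- names(alignments)
  structure(list(loci = reports, thresholds = thresholds,
                 seed = as.integer(seed), schemaVersion = "1.0"),
            class = "locusComparison")
}

runSingleLocus <- function(locus, alignment, taxonomy, thresholds, windows,
                           bootstrapReplicates, seed, congruenceRanks) {
  stopifnot(is(alignment, "GeneAlignment"))

  # conservation
  track <- conservationTrack(alignment, windows)
  varCounts <- variabilityCounts(alignment)
  conservation <- list(
    meanRsPercent = meanConservationPercent(track$rs),
    windowMeanPercent = lapply(track$windows, function(w)
      100 * mean(w$fraction)),
    totalVariableSites = varCounts$totalVariableSites,
    singletonVariableSites = varCounts$singletonVariableSites,
    heteroplasmicCells = heteroplasmyCount(alignment))

  # distance suite (x100 presentation throughout the report)
  subsets <- c("all", "pos1", "pos2", "pos3")
  distances <- list()
  for (metric in c("p", "k2p")) {
    distances[[metric]] <- lapply(stats::setNames(subsets, subsets),
                                  function(sub) {
      dm <- pairwiseMatrix(alignment, metric, sub)
      s <- distanceSummary(dm, x100 = TRUE)
      bs <- bootstrapSE(alignment, metric, sub,
                        replicates = bootstrapReplicates, seed = seed)
      c(s[c("mean", "max", "min")],
        list(se = 100 * bs$se, saturatedExcluded = s$saturatedExcluded))
    })
  }
  for (metric in c("dS", "dN")) {
    dm <- pairwiseMatrix(alignment, metric)
    s <- distanceSummary(dm, x100 = TRUE)
    bs <- bootstrapSE(alignment, metric, replicates = bootstrapReplicates,
                      seed = seed)
    distances[[metric]] <- c(s[c("mean", "max", "min")],
                             list(se = 100 * bs$se,
                                  saturatedExcluded = s$saturatedExcluded))
  }

  # discrimination on the overall K2P matrix
  k2p <- pairwiseMatrix(alignment, "k2p", "all")
  pairs <- labelPairs(k2p, taxonomy)
  thresholdReports <- lapply(thresholds, function(t) {
    ct <- contingencyTable(pairs, t)
    c(as.list(c(nAB = ct@nAB, naB = ct@naB, nAb = ct@nAb, nab = ct@nab)),
      as.list(contingencyMarginals(ct)),
      as.list(thresholdMetrics(ct)))
  })
  names(thresholdReports) <- sprintf("t%.1f", thresholds)
  bothClasses <- any(pairs$sameSpecies) && any(!pairs$sameSpecies)
  gap <- if (bothClasses) gapScan(pairs, candidateThresholds = thresholds)
    else NULL
  roc <- if (bothClasses) rocCurve(pairs) else NULL

  # phylogeny + congruence
  congr <- NULL
  tree <- NULL
  if (nSequences(alignment) >= 3L && !any(k2p@saturated)) {
    tree <- njTree(k2p)
    congr <- congruenceAcrossRanks(tree, taxonomy, congruenceRanks)
  } else {
    warning(sprintf(
      "locus %s: tree/congruence skipped (<3 sequences or saturated pairs)",
      locus))
  }

  list(locus = locus,
       nSequences = nSequences(alignment),
       alignmentLength = alignmentLength(alignment),
       conservation = conservation,
       distances = distances,
       thresholds = thresholdReports,
       gap = if (is.null(gap)) NULL else
         gap[c("maxIntra", "minInter", "gapInterval", "thresholdsInGap")],
       roc = if (is.null(roc)) NULL else roc[c("auc", "aucSE")],
       congruence = congr,
       tree = tree,
       seed = as.integer(seed))
}

#' Write a locus comparison report as JSON
#'
#' Numbers are written at full precision; the NJ trees are embedded as
#' Newick strings. Regenerating the report from the same inputs and seed
#' yields byte-identical output.
#'
#' @param comparison A `locusComparison` from [runLocusComparison()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLocusReport <- function(comparison, path) {
  stopifnot(inherits(comparison, "locusComparison"))
  out <- comparison
  out$loci <- lapply(out$loci, function(rep) {
    if (!is.null(rep$tree))
      rep$tree <- ape::write.tree(rep$tree)
    rep
  })
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
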