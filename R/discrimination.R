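#' @include distances.R
NULL

#' Label pairwise distances as same- or different-species
#'
#' Every unordered pair of samples from the distance matrix is labelled
#' using the taxonomy's collapse map: two samples are same-species when
#' their collapsed species labels agree, so subspecies of one species
#' compare as same-species. Distances are reported on the x100 scale, the
#' convention for barcoding thresholds. Saturated pairs are dropped (their
#' count is attached as attribute `droppedSaturated`).
#'
#' @param dm A [DistanceMatrix-class] (typically K2P).
#' @param taxonomy A [TaxonomyTable-class] resolving every matrix id.
#' @return data.frame with columns `id1`, `id2`, `distance` (x100) and
#'   `sameSpecies`.
#' @export
labelPairs <- function(dm, taxonomy) {
  stopifnot(is(dm, "DistanceMatrix"), is(taxonomy, "TaxonomyTable"))
  ids <- sampleIds(dm)
  species <- collapseSpecies(taxonomy, ids)   # errors on unresolvable ids
  v <- distanceValues(dm, x100 = TRUE)
  pr <- pairIndices(length(ids))
  out <- data.frame(id1 = ids[pr[, 1L]], id2 = ids[pr[, 2L]],
                    distance = v[pr],
                    sameSpecies = species[pr[, 1L]] == species[pr[, 2L]])
  dropped <- sum(is.na(out$distance))
  out <- out[!is.na(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "droppedSaturated") <- dropped
  out
}

#' Threshold contingency table for labelled pairs
#'
#' A pair is positive (same-species call) when its distance falls strictly
#' below the threshold; a value exactly at the threshold is negative. The
#' non-strict orientation is available via `strict = FALSE`.
#'
#' @param pairs data.frame from [labelPairs()].
#' @param threshold K2P (x100) threshold.
#' @param strict Use strict `<` (default) rather than `<=`.
#' @return A [ContingencyTable-class].
#' @export
contingencyTable <- function(pairs, threshold, strict = TRUE) {
  if (!nrow(pairs)) stop("no labelled pairs")
  pos <- if (strict) pairs$distance < threshold else
    pairs$distance <= threshold
  new("ContingencyTable",
      nAB = sum(pos & pairs$sameSpecies),
      naB = sum(pos & !pairs$sameSpecies),
      nAb = sum(!pos & pairs$sameSpecies),
      nab = sum(!pos & !pairs$sameSpecies),
      threshold = threshold)
}

#' Build a ContingencyTable directly from cell counts
#'
#' Accepts either the four cells, or the marginals-plus-error-cells form in
#' which published threshold tables are often printed (`nB`, `nb`, `naB`,
#' `nAb`), from which `nAB = nB - naB` and `nab = nb - nAb`.
#'
#' @param nAB,naB,nAb,nab The four cells.
#' @param nB,nb Column totals (positive / negative calls), used when `nAB` /
#'   `nab` are not given.
#' @param threshold Optional threshold annotation.
#' @return A [ContingencyTable-class].
#' @export
contingencyFromCounts <- function(nAB = NULL, naB, nAb, nab = NULL,
                                  nB = NULL, nb = NULL, threshold = NA_real_) {
  if (is.null(nAB)) {
    if (is.null(nB)) stop("need either nAB or nB")
    nAB <- nB - naB
  }
  if (is.null(nab)) {
    if (is.null(nb)) stop("need either nab or nb")
    nab <- nb - nAb
  }
  new("ContingencyTable", nAB = nAB, naB = naB, nAb = nAb, nab = nab,
      threshold = threshold)
}

#' Marginals of a contingency table
#'
#' @param ct A [ContingencyTable-class].
#' @return Named numeric with `nA`, `na`, `nB`, `nb`, `n`.
#' @export
contingencyMarginals <- function(ct) {
  stopifnot(is(ct, "ContingencyTable"))
  c(nA = ct@nAB + ct@nAb, na = ct@naB + ct@nab,
    nB = ct@nAB + ct@naB, nb = ct@nAb + ct@nab,
    n = ct@nAB + ct@naB + ct@nAb + ct@nab)
}

#' Discrimination metrics from a contingency table
#'
#' False positive rate `naB/na`, false negative rate `nAb/nA`, sensitivity
#' `nAB/nA`, specificity `nab/na`, positive predictive value `nAB/nB` and
#' negative predictive value `nab/nb`. A metric whose denominator is zero is
#' reported as `NA` (undefined), not as an error.
#'
#' @param ct A [ContingencyTable-class].
#' @return Named numeric vector with the six metrics.
#' @export
thresholdMetrics <- function(ct) {
  m <- contingencyMarginals(ct)
  ratio <- function(num, den) {
    den <- unname(den)
    if (den > 0) num / den else NA_real_
  }
  c(fpRate = ratio(ct@naB, m["na"]),
    fnRate = ratio(ct@nAb, m["nA"]),
    sensitivity = ratio(ct@nAB, m["nA"]),
    specificity = ratio(ct@nab, m["na"]),
    ppv = ratio(ct@nAB, m["nB"]),
    npv = ratio(ct@nab, m["nb"]))
}

#' Barcoding-gap scan
#'
#' Reports the largest intraspecific (same-species) and smallest
#' interspecific (different-species) distance; the gap interval is
#' `(maxIntra, minInter)` when it has positive width, otherwise empty. A
#' histogram of both classes (default bin width 0.1 on the x100 scale) is
#' returned alongside.
#'
#' @param pairs data.frame from [labelPairs()], with both classes present.
#' @param binWidth Histogram bin width (x100 scale).
#' @param candidateThresholds Thresholds of interest to annotate (defaults
#'   to the classical 1.5 / 2.0 / 2.5).
#' @return List with `maxIntra`, `minInter`, `gapInterval` (length-2 numeric
#'   or NULL), `candidateThresholds`, `thresholdsInGap`, `histogram`.
#' @export
gapScan <- function(pairs, binWidth = 0.1,
                    candidateThresholds = c(1.5, 2.0, 2.5)) {
  if (!any(pairs$sameSpecies) || !any(!pairs$sameSpecies))
    stop("need at least one same-species and one different-species pair")
  maxIntra <- max(pairs$distance[pairs$sameSpecies])
  minInter <- min(pairs$distance[!pairs$sameSpecies])
  gap <- if (maxIntra < minInter) c(maxIntra, minInter) else NULL
  breaks <- seq(0, ceiling(max(pairs$distance) / binWidth + 1) * binWidth,
                by = binWidth)
  histCounts <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$counts
  }
  histogram <- data.frame(
    binStart = breaks[-length(breaks)], binEnd = breaks[-1L],
    intra = histCounts(pairs$distance[pairs$sameSpecies]),
    inter = histCounts(pairs$distance[!pairs$sameSpecies]))
  inGap <- if (is.null(gap)) candidateThresholds[0] else
    candidateThresholds[candidateThresholds > gap[1L] &
                        candidateThresholds < gap[2L]]
  list(maxIntra = maxIntra, minInter = minInter, gapInterval = gap,
       candidateThresholds = candidateThresholds, thresholdsInGap = inGap,
       histogram = histogram)
}

#' ROC curve and AUC for species discrimination
#'
#' Smaller distances indicate a positive (same-species) call. The threshold
#' sweeps over every distinct observed distance; each point is
#' (1 - specificity, sensitivity). The AUC is computed by the trapezoid rule
#' and equals the Mann-Whitney statistic `U / (nA * na)` with ties counted
#' one half. Its standard error uses the Hanley-McNeil formula under the
#' non-parametric (distribution-free) assumption.
#'
#' @param pairs data.frame from [labelPairs()] with both classes present.
#' @param strict Strict `<` threshold comparison (both orientations give the
#'   same trapezoid AUC; the point set differs only in anchoring).
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `aucSE`, `nIntra`, `nInter`.
#' @export
rocCurve <- function(pairs, strict = TRUE) {
  intra <- pairs$distance[pairs$sameSpecies]
  inter <- pairs$distance[!pairs$sameSpecies]
  nA <- length(intra); na <- length(inter)
  if (nA == 0L || na == 0L)
    stop("ROC needs both same-species and different-species pairs")
  ts <- c(sort(unique(pairs$distance)), Inf)
  cmp <- if (strict) `<` else `<=`
  tpr <- vapply(ts, function(t) mean(cmp(intra, t)), numeric(1))
  fpr <- vapply(ts, function(t) mean(cmp(inter, t)), numeric(1))
  points <- data.frame(threshold = ts, fpr = fpr, tpr = tpr)
  if (points$fpr[1L] > 0 || points$tpr[1L] > 0)
    points <- rbind(data.frame(threshold = -Inf, fpr = 0, tpr = 0), points)
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1L) + utils::tail(points$tpr, -1L)) / 2)
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  aucSE <- sqrt((A * (1 - A) + (nA - 1) * (Q1 - A^2) +
                   (na - 1) * (Q2 - A^2)) / (nA * na))
  list(points = points, auc = auc, aucSE = aucSE, nIntra = nA, nInter = na)
}

#' Remove exact-duplicate sequences from an alignment
#'
#' Keeps the first occurrence of each distinct sequence string, the
#' pre-processing used before pooling intra- and interspecific data sets
#' into one combined database.
#'
#' @param alignment A [GeneAlignment-class].
#' @return A [GeneAlignment-class] with duplicates removed (a message
#'   reports how many were dropped).
#' @export
deduplicateSequences <- function(alignment) {
  stopifnot(is(alignment, "GeneAlignment"))
  s <- as.character(alignment@seqs)
  keep <- !duplicated(s)
  if (all(keep)) return(alignment)
  message(sprintf("removed %d duplicate sequence(s)", sum(!keep)))
  GeneAlignment(s[keep], siteMap = siteMap(alignment))
}
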