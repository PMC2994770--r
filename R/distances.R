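#' @include alignment-io.R genetic-code.R
NULL

#' Unordered pair indices
#'
#' Enumerates the n(n-1)/2 unordered pairs (i < j) in row-major order; this
#' is the pair set every pairwise analysis in the package iterates over
#' (e.g. 1,343 pooled sequences give 901,153 comparisons).
#'
#' @param n Number of samples.
#' @return Two-column integer matrix with columns `i`, `j`.
#' @export
pairIndices <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  cbind(i = rep.int(seq_len(n - 1L), times = (n - 1L):1L),
        j = sequence((n - 1L):1L, from = 2:n))
}

# Integer base codes A=1 C=2 G=3 T=4 (NA for anything else).
baseCodes <- function(m) {
  codes <- match(m, c("A", "C", "G", "T"))
  dim(codes) <- dim(m)
  dimnames(codes) <- dimnames(m)
  codes
}

# Transitions stay within purines {A,G} (odd codes) or pyrimidines {C,T}.
isTransition <- function(c1, c2) {
  (c1 != c2) & ((c1 %% 2L) == (c2 %% 2L))
}

#' Complete deletion of gapped / ambiguous columns
#'
#' Removes every column that contains a gap or an IUPAC ambiguity symbol in
#' any sequence, the standard pre-processing before distance computation.
#' With `codonAware = TRUE` whole codons are removed whenever any of their
#' three columns would be, keeping the reading frame intact for
#' synonymous/non-synonymous analysis. The returned alignment's
#' [siteMap()] records the surviving original columns.
#'
#' @param alignment A [GeneAlignment-class].
#' @param codonAware Remove whole codons rather than single columns.
#' @param frameOffset Frame used when `codonAware = TRUE`.
#' @return A [GeneAlignment-class] restricted to clean columns.
#' @export
completeDeletion <- function(alignment, codonAware = FALSE, frameOffset = 0L) {
  stopifnot(is(alignment, "GeneAlignment"), nSequences(alignment) >= 2L)
  m <- alignmentMatrix(alignment)
  dirty <- apply(m, 2L, function(col) any(!col %in% c("A", "C", "G", "T")))
  if (codonAware) {
    cls <- sitePositionClasses(alignment, frameOffset)
    codon <- (siteMap(alignment) - 1L - frameOffset) %/% 3L
    codon[is.na(cls)] <- NA_integer_
    dirtyCodons <- unique(codon[dirty & !is.na(codon)])
    drop <- is.na(codon) | codon %in% dirtyCodons
  } else {
    drop <- dirty
  }
  if (all(drop))
    stop("complete deletion removed every column")
  keep <- which(!drop)
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  GeneAlignment(seqs, siteMap = siteMap(alignment)[keep])
}

checkPair <- function(s1, s2) {
  s1 <- strsplit(normaliseSymbols(as.character(s1)), "")[[1L]]
  s2 <- strsplit(normaliseSymbols(as.character(s2)), "")[[1L]]
  if (length(s1) != length(s2)) stop("sequences must have equal length")
  list(c1 = match(s1, c("A", "C", "G", "T")),
       c2 = match(s2, c("A", "C", "G", "T")))
}

#' Nucleotide p-distance between two aligned sequences
#'
#' Proportion of differing sites over the compared positions. Positions
#' where either sequence holds a gap or ambiguity are excluded.
#'
#' @param s1,s2 Aligned sequences (strings of equal length).
#' @param positions Optional integer vector of 1-based positions to compare
#'   (e.g. one set from [codonMask()]); default all.
#' @param x100 Present the value multiplied by 100.
#' @return Numeric distance.
#' @export
pDistance <- function(s1, s2, positions = NULL, x100 = FALSE) {
  p <- checkPair(s1, s2)
  idx <- if (is.null(positions)) seq_along(p$c1) else as.integer(positions)
  if (any(idx < 1L | idx > length(p$c1))) stop("positions out of bounds")
  ok <- !is.na(p$c1[idx]) & !is.na(p$c2[idx])
  idx <- idx[ok]
  if (!length(idx)) stop("no comparable positions in the requested subset")
  d <- mean(p$c1[idx] != p$c2[idx])
  if (x100) 100 * d else d
}

k2pFromPQ <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- rep(NA_real_, length(P))
  ok <- w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  d
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P the transition and Q the transversion proportion over the compared
#' positions, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When either log
#' argument is non-positive the pair is saturated and an error of class
#' `saturationError` is raised (matrix builders catch it and flag the pair).
#'
#' @inheritParams pDistance
#' @return Numeric distance.
#' @export
k2pDistance <- function(s1, s2, positions = NULL, x100 = FALSE) {
  p <- checkPair(s1, s2)
  idx <- if (is.null(positions)) seq_along(p$c1) else as.integer(positions)
  if (any(idx < 1L | idx > length(p$c1))) stop("positions out of bounds")
  ok <- !is.na(p$c1[idx]) & !is.na(p$c2[idx])
  idx <- idx[ok]
  if (!length(idx)) stop("no comparable positions in the requested subset")
  c1 <- p$c1[idx]; c2 <- p$c2[idx]
  diff <- c1 != c2
  P <- mean(diff & isTransition(c1, c2))
  Q <- mean(diff & !isTransition(c1, c2))
  d <- k2pFromPQ(P, Q)
  if (is.na(d))
    stop(structure(class = c("saturationError", "error", "condition"),
                   list(message = sprintf(
                     "K2P undefined (saturated) at P = %.4f, Q = %.4f", P, Q),
                     call = sys.call())))
  if (x100) 100 * d else d
}

positionsForSubset <- function(alignment, positions, frameOffset = 0L) {
  positions <- match.arg(positions, c("all", "pos1", "pos2", "pos3"))
  if (positions == "all") return(seq_len(alignmentLength(alignment)))
  cls <- sitePositionClasses(alignment, frameOffset)
  which(!is.na(cls) & cls == as.integer(substr(positions, 4L, 4L)))
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all n(n-1)/2 unordered pairwise distances after gap/ambiguity
#' removal. Complete deletion (a column with a gap or ambiguity in any
#' sequence is dropped for all pairs) is the default; pairwise deletion is
#' available as a non-default option. For `dS`/`dN` the deletion is
#' codon-aware and codons containing a stop in any sequence are skipped.
#'
#' @param alignment A [GeneAlignment-class] with at least 2 sequences.
#' @param metric `"p"`, `"k2p"`, `"dS"` or `"dN"`.
#' @param positions `"all"`, `"pos1"`, `"pos2"` or `"pos3"` (codon-position
#'   partition; ignored for `dS`/`dN`, which are whole-codon metrics).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @param frameOffset Frame for the codon-position partition.
#' @param scaleX100 Record the x100 presentation flag on the result.
#' @return A [DistanceMatrix-class]. Saturated K2P pairs hold `NA` and are
#'   flagged.
#' @export
pairwiseMatrix <- function(alignment,
                           metric = c("p", "k2p", "dS", "dN"),
                           positions = c("all", "pos1", "pos2", "pos3"),
                           deletion = c("complete", "pairwise"),
                           frameOffset = 0L, scaleX100 = FALSE) {
  metric <- match.arg(metric)
  positions <- match.arg(positions)
  deletion <- match.arg(deletion)
  stopifnot(is(alignment, "GeneAlignment"), nSequences(alignment) >= 2L)

  if (metric %in% c("dS", "dN"))
    return(ngPairwiseMatrix(alignment, metric, deletion, frameOffset,
                            scaleX100))

  aln <- if (deletion == "complete")
    completeDeletion(alignment) else alignment
  codes <- baseCodes(alignmentMatrix(aln))
  idx <- positionsForSubset(aln, positions, frameOffset)
  if (!length(idx))
    stop("empty position subset after deletion")
  codes <- codes[, idx, drop = FALSE]
  n <- nrow(codes)
  pr <- pairIndices(n)
  vals <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(vals))
  for (k in seq_len(nrow(pr))) {
    c1 <- codes[pr[k, 1L], ]; c2 <- codes[pr[k, 2L], ]
    ok <- !is.na(c1) & !is.na(c2)
    if (!any(ok)) {
      vals[pr[k, 1L], pr[k, 2L]] <- vals[pr[k, 2L], pr[k, 1L]] <- NA
      sat[pr[k, 1L], pr[k, 2L]] <- sat[pr[k, 2L], pr[k, 1L]] <- TRUE
      next
    }
    c1 <- c1[ok]; c2 <- c2[ok]
    diff <- c1 != c2
    if (metric == "p") {
      d <- mean(diff)
    } else {
      P <- mean(diff & isTransition(c1, c2))
      Q <- mean(diff & !isTransition(c1, c2))
      d <- k2pFromPQ(P, Q)
    }
    vals[pr[k, 1L], pr[k, 2L]] <- d
    vals[pr[k, 2L], pr[k, 1L]] <- d
    if (is.na(d)) {
      sat[pr[k, 1L], pr[k, 2L]] <- TRUE
      sat[pr[k, 2L], pr[k, 1L]] <- TRUE
    }
  }
  new("DistanceMatrix", values = vals, metric = metric,
      positionSubset = positions, scaleX100 = scaleX100, saturated = sat)
}

ngPairwiseMatrix <- function(alignment, metric, deletion, frameOffset,
                             scaleX100) {
  tabs <- ngTables()
  aln <- completeDeletion(alignment, codonAware = TRUE,
                          frameOffset = frameOffset)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  codons <- ncol(m) %/% 3L
  ids <- rownames(m)
  codIdx <- matrix(0L, n, codons)
  for (i in seq_len(n)) {
    seq <- paste(m[i, ], collapse = "")
    codIdx[i, ] <- codonIndex(splitCodons(seq))
  }
  stopMask <- matrix(tabs$isStop[codIdx], n, codons)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(vals))
  pr <- pairIndices(n)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    use <- !stopMask[i, ] & !stopMask[j, ]
    if (!any(use)) { vals[i, j] <- vals[j, i] <- NA
                     sat[i, j] <- sat[j, i] <- TRUE; next }
    i1 <- codIdx[i, use]; i2 <- codIdx[j, use]
    num <- if (metric == "dS") tabs$sd[cbind(i1, i2)] else
      tabs$nd[cbind(i1, i2)]
    Sbar <- (sum(tabs$sPerCodon[i1]) + sum(tabs$sPerCodon[i2])) / 2
    denom <- if (metric == "dS") Sbar else 3 * length(i1) - Sbar
    if (denom <= 0) { vals[i, j] <- vals[j, i] <- NA
                      sat[i, j] <- sat[j, i] <- TRUE; next }
    d <- sum(num, na.rm = TRUE) / denom
    vals[i, j] <- vals[j, i] <- d
  }
  new("DistanceMatrix", values = vals, metric = metric,
      positionSubset = "all", scaleX100 = scaleX100, saturated = sat)
}

#' Summary statistics of a distance matrix
#'
#' Mean, maximum and minimum over the unordered pairs, excluding saturated
#' pairs (their count is reported).
#'
#' @param dm A [DistanceMatrix-class].
#' @param x100 Scale; defaults to the matrix's own flag.
#' @return List with `mean`, `max`, `min`, `nPairs`, `saturatedExcluded`.
#' @export
distanceSummary <- function(dm, x100 = NULL) {
  stopifnot(is(dm, "DistanceMatrix"))
  v <- distanceValues(dm, x100)
  ut <- upper.tri(v)
  vals <- v[ut]
  nsat <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("every pair is saturated; no summary available")
  list(mean = mean(vals), max = max(vals), min = min(vals),
       nPairs = sum(ut), saturatedExcluded = nsat)
}

#' Bootstrap standard error of the mean pairwise distance
#'
#' Columns of the complete-deletion alignment (codons, for `dS`/`dN`) are
#' resampled with replacement; the overall mean pairwise distance is
#' recomputed per replicate and the standard error is the standard
#' deviation across replicates. Deterministic given `seed`. Saturated pairs
#' within a replicate are excluded from that replicate's mean.
#'
#' @inheritParams pairwiseMatrix
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return List with `estimate` (full-data mean distance), `se`,
#'   `replicates`, `seed`, `metric`, `positions`.
#' @export
bootstrapSE <- function(alignment, metric = c("p", "k2p", "dS", "dN"),
                        positions = c("all", "pos1", "pos2", "pos3"),
                        replicates = 1000L, seed, frameOffset = 0L) {
  metric <- match.arg(metric)
  positions <- match.arg(positions)
  stopifnot(is(alignment, "GeneAlignment"), nSequences(alignment) >= 2L)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  set.seed(as.integer(seed))

  if (metric %in% c("dS", "dN"))
    return(ngBootstrapSE(alignment, metric, replicates, seed, frameOffset))

  aln <- completeDeletion(alignment)
  codes <- baseCodes(alignmentMatrix(aln))
  idx <- positionsForSubset(aln, positions, frameOffset)
  codes <- codes[, idx, drop = FALSE]
  L <- ncol(codes)
  n <- nrow(codes)
  pr <- pairIndices(n)
  np <- nrow(pr)
  TS <- matrix(0, np, L)
  TV <- matrix(0, np, L)
  for (k in seq_len(np)) {
    c1 <- codes[pr[k, 1L], ]; c2 <- codes[pr[k, 2L], ]
    diff <- c1 != c2
    TS[k, ] <- as.numeric(diff & isTransition(c1, c2))
    TV[k, ] <- as.numeric(diff & !isTransition(c1, c2))
  }
  W <- stats::rmultinom(replicates, L, rep(1 / L, L))
  Pm <- (TS %*% W) / L
  Qm <- (TV %*% W) / L
  if (metric == "p") {
    reps <- colMeans(Pm + Qm)
    est <- mean(rowSums(TS + TV) / L)
  } else {
    dmat <- matrix(k2pFromPQ(Pm, Qm), np, replicates)
    reps <- colMeans(dmat, na.rm = TRUE)
    est <- mean(k2pFromPQ(rowSums(TS) / L, rowSums(TV) / L), na.rm = TRUE)
  }
  list(estimate = est, se = stats::sd(reps), replicates = replicates,
       seed = as.integer(seed), metric = metric, positions = positions)
}

ngBootstrapSE <- function(alignment, metric, replicates, seed, frameOffset) {
  tabs <- ngTables()
  aln <- completeDeletion(alignment, codonAware = TRUE,
                          frameOffset = frameOffset)
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  codons <- ncol(m) %/% 3L
  codIdx <- t(vapply(seq_len(n), function(i)
    codonIndex(splitCodons(paste(m[i, ], collapse = ""))),
    integer(codons)))
  stopAny <- colSums(matrix(tabs$isStop[codIdx], n, codons)) > 0
  codIdx <- codIdx[, !stopAny, drop = FALSE]
  nc <- ncol(codIdx)
  if (nc == 0L) stop("no stop-free codon columns to resample")
  pr <- pairIndices(n)
  np <- nrow(pr)
  NUM <- matrix(0, np, nc)   # per-pair per-codon sd or nd
  for (k in seq_len(np)) {
    i1 <- codIdx[pr[k, 1L], ]; i2 <- codIdx[pr[k, 2L], ]
    x <- if (metric == "dS") tabs$sd[cbind(i1, i2)] else
      tabs$nd[cbind(i1, i2)]
    x[is.na(x)] <- 0
    NUM[k, ] <- x
  }
  SMAT <- matrix(tabs$sPerCodon[codIdx], n, nc)
  W <- stats::rmultinom(replicates, nc, rep(1 / nc, nc))
  numW <- NUM %*% W                       # np x reps
  sW <- SMAT %*% W                        # n x reps
  SbarW <- (sW[pr[, 1L], , drop = FALSE] + sW[pr[, 2L], , drop = FALSE]) / 2
  totalSites <- matrix(3 * nc, np, replicates)
  denomW <- if (metric == "dS") SbarW else totalSites - SbarW
  dW <- numW / denomW
  dW[!is.finite(dW)] <- NA
  reps <- colMeans(dW, na.rm = TRUE)
  Sbar0 <- (rowSums(SMAT)[pr[, 1L]] + rowSums(SMAT)[pr[, 2L]]) / 2
  denom0 <- if (metric == "dS") Sbar0 else 3 * nc - Sbar0
  est <- mean(rowSums(NUM) / denom0, na.rm = TRUE)
  list(estimate = est, se = stats::sd(reps), replicates = replicates,
       seed = as.integer(seed), metric = metric, positions = "all")
}

#' Write a distance matrix to disk
#'
#' `"square"` writes a tab-delimited square matrix with a header row of
#' sample ids (PHYLIP-square compatible); `"long"` writes one row per
#' unordered pair with columns `id1, id2, metric, subset, value`.
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @param x100 Scale; defaults to the matrix's own flag.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path, format = c("square", "long"),
                                x100 = NULL) {
  format <- match.arg(format)
  v <- distanceValues(dm, x100)
  if (format == "square") {
    utils::write.table(v, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    pr <- pairIndices(nrow(v))
    out <- data.frame(id1 = rownames(v)[pr[, 1L]],
                      id2 = rownames(v)[pr[, 2L]],
                      metric = dm@metric, subset = dm@positionSubset,
                      value = v[pr])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
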