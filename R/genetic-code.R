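#' @include alignment-io.R
NULL

# Nei-Gojobori machinery under the vertebrate mitochondrial genetic code
# (AGA/AGG and TAA/TAG are stops, ATA is Met, TGA is Trp). Codons are
# indexed 1..64 as 16*(b1-1) + 4*(b2-1) + b3 with A=1, C=2, G=3, T=4.

NG_BASES <- c("A", "C", "G", "T")

codonIndex <- function(codons) {
  b <- matrix(match(unlist(strsplit(codons, ""), use.names = FALSE),
                    NG_BASES), ncol = 3L, byrow = TRUE)
  16L * (b[, 1L] - 1L) + 4L * (b[, 2L] - 1L) + b[, 3L]
}

codonString <- function(idx) {
  idx <- idx - 1L
  paste0(NG_BASES[idx %/% 16L + 1L],
         NG_BASES[(idx %/% 4L) %% 4L + 1L],
         NG_BASES[idx %% 4L + 1L])
}

# Orderings of k differing positions, k <= 3 (pathway averaging).
PATH_ORDERINGS <- list(list(1L),
                       list(c(1L, 2L), c(2L, 1L)),
                       list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

ngEnv <- new.env(parent = emptyenv())

# Builds and caches: the amino-acid translation of the 64 codons under the
# vertebrate mitochondrial code, per-codon synonymous site counts, and the
# 64 x 64 pathway-averaged synonymous/non-synonymous difference tables.
ngTables <- function() {
  if (!is.null(ngEnv$tables)) return(ngEnv$tables)
  gc2 <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  allCodons <- codonString(1:64)
  aa <- unname(gc2[allCodons])
  isStop <- aa == "*"

  # Fractional synonymous sites per codon: at each position, the fraction of
  # the three single-base alternatives whose codon encodes the same amino
  # acid. Changes to stop codons land in the non-synonymous fraction.
  sPerCodon <- rep(NA_real_, 64L)
  for (ci in which(!isStop)) {
    codon <- strsplit(allCodons[ci], "")[[1L]]
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(NG_BASES, codon[pos])) {
        mutant <- codon
        mutant[pos] <- alt
        mi <- codonIndex(paste(mutant, collapse = ""))
        if (!isStop[mi] && aa[mi] == aa[ci]) s <- s + 1 / 3
      }
    }
    sPerCodon[ci] <- s
  }

  sd <- matrix(NA_real_, 64L, 64L)
  nd <- matrix(NA_real_, 64L, 64L)
  for (i in which(!isStop)) {
    ci <- strsplit(allCodons[i], "")[[1L]]
    for (j in which(!isStop)) {
      cj <- strsplit(allCodons[j], "")[[1L]]
      diffPos <- which(ci != cj)
      k <- length(diffPos)
      if (k == 0L) { sd[i, j] <- 0; nd[i, j] <- 0; next }
      sdSum <- 0; ndSum <- 0; nPaths <- 0L
      for (ord in PATH_ORDERINGS[[k]]) {
        cur <- ci
        pathS <- 0; pathN <- 0; valid <- TRUE
        for (pos in diffPos[ord]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          fromI <- codonIndex(paste(cur, collapse = ""))
          toI <- codonIndex(paste(nxt, collapse = ""))
          if (isStop[toI]) { valid <- FALSE; break }
          if (aa[fromI] == aa[toI]) pathS <- pathS + 1 else pathN <- pathN + 1
          cur <- nxt
        }
        if (valid) {
          sdSum <- sdSum + pathS
          ndSum <- ndSum + pathN
          nPaths <- nPaths + 1L
        }
      }
      if (nPaths > 0L) {
        sd[i, j] <- sdSum / nPaths
        nd[i, j] <- ndSum / nPaths
      }
    }
  }
  ngEnv$tables <- list(aa = aa, isStop = isStop, sPerCodon = sPerCodon,
                       sd = sd, nd = nd)
  ngEnv$tables
}

splitCodons <- function(seq) {
  seq <- normaliseSymbols(as.character(seq))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length must be divisible by 3 for codon analysis")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

#' Nei-Gojobori synonymous / non-synonymous site counts
#'
#' For each codon the synonymous site count is the sum over its three
#' positions of the fraction of the three single-base alternatives that are
#' synonymous under the vertebrate mitochondrial code; changes to stop
#' codons count as non-synonymous. `S + N = 3 * codons` by construction.
#'
#' @param codonSequence In-frame DNA string, length divisible by 3, plain
#'   A/C/G/T (run [completeDeletion()] with `codonAware = TRUE` first).
#' @param lenient Skip stop codons instead of raising an error.
#' @return List with fractional `S`, `N` and the `codons` counted.
#' @export
ngSiteCounts <- function(codonSequence, lenient = FALSE) {
  tabs <- ngTables()
  codons <- splitCodons(codonSequence)
  if (any(grepl("[^ACGT]", codons)))
    stop("codon sequence must contain only A/C/G/T")
  idx <- codonIndex(codons)
  stops <- tabs$isStop[idx]
  if (any(stops)) {
    if (!lenient)
      stop(sprintf("internal stop codon(s) at codon position(s): %s",
                   paste(which(stops), collapse = ", ")))
    idx <- idx[!stops]
  }
  S <- sum(tabs$sPerCodon[idx])
  list(S = S, N = 3 * length(idx) - S, codons = length(idx))
}

#' Pathway-averaged synonymous / non-synonymous differences between codons
#'
#' For k differing positions, counts are averaged over the orderings of
#' single-base steps; any pathway passing through a stop codon is excluded.
#' When at least one valid pathway exists, `sd + nd = k`.
#'
#' @param codon1,codon2 Three-letter DNA codons, neither a stop.
#' @return Named numeric `c(sd=, nd=)`.
#' @export
ngDifferences <- function(codon1, codon2) {
  tabs <- ngTables()
  codon1 <- normaliseSymbols(codon1); codon2 <- normaliseSymbols(codon2)
  if (nchar(codon1) != 3L || nchar(codon2) != 3L ||
      grepl("[^ACGT]", codon1) || grepl("[^ACGT]", codon2))
    stop("codons must be three plain A/C/G/T letters")
  i <- codonIndex(codon1); j <- codonIndex(codon2)
  if (tabs$isStop[i] || tabs$isStop[j])
    stop("stop codons have no synonymous/non-synonymous decomposition")
  sd <- tabs$sd[i, j]; nd <- tabs$nd[i, j]
  if (is.na(sd))
    stop(sprintf("all mutational pathways between %s and %s pass through stops",
                 codon1, codon2))
  c(sd = sd, nd = nd)
}

#' Nei-Gojobori dS and dN between two aligned coding sequences
#'
#' Synonymous differences per synonymous site and non-synonymous differences
#' per non-synonymous site, in the p-distance flavour (no multiple-hit
#' correction): `dS = sum(sd) / mean(S1, S2)` and `dN = sum(nd) /
#' mean(N1, N2)`. Codon pairs whose every mutational pathway passes through
#' a stop are skipped from the numerators (their count is reported).
#'
#' On very short sequences dS can exceed 1 because the denominator is a
#' fractional site count; this is a property of the estimator, not an error.
#'
#' @param s1,s2 Aligned in-frame DNA strings (equal length, divisible by 3).
#' @param lenient Skip codon columns where either sequence holds a stop
#'   codon (both numerator and site counts ignore them).
#' @param x100 Present results multiplied by 100.
#' @return List with `dS`, `dN`, `sdTotal`, `ndTotal`, `skippedCodons`.
#' @export
ngDistance <- function(s1, s2, lenient = FALSE, x100 = FALSE) {
  tabs <- ngTables()
  c1 <- splitCodons(s1); c2 <- splitCodons(s2)
  if (length(c1) != length(c2))
    stop("sequences must have equal length")
  i1 <- codonIndex(c1); i2 <- codonIndex(c2)
  stops <- tabs$isStop[i1] | tabs$isStop[i2]
  if (any(stops)) {
    if (!lenient)
      stop("internal stop codon(s); use lenient = TRUE to skip them")
    i1 <- i1[!stops]; i2 <- i2[!stops]
  }
  if (!length(i1)) stop("no codons left to compare")
  sd <- tabs$sd[cbind(i1, i2)]
  nd <- tabs$nd[cbind(i1, i2)]
  skipped <- sum(is.na(sd))
  S1 <- sum(tabs$sPerCodon[i1]); S2 <- sum(tabs$sPerCodon[i2])
  Sbar <- (S1 + S2) / 2
  Nbar <- 3 * length(i1) - Sbar
  if (Sbar <= 0 || Nbar <= 0)
    stop("mean synonymous or non-synonymous site count is zero")
  scale <- if (x100) 100 else 1
  list(dS = scale * sum(sd, na.rm = TRUE) / Sbar,
       dN = scale * sum(nd, na.rm = TRUE) / Nbar,
       sdTotal = sum(sd, na.rm = TRUE), ndTotal = sum(nd, na.rm = TRUE),
       skippedCodons = skipped)
}
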