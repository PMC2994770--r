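#' @include alignment-io.R
NULL

#' Per-site base frequencies under the heteroplasmy rule
#'
#' Each unambiguous base (A, C, G, T) is counted once; IUPAC ambiguity
#' symbols (heteroplasmic calls) and gaps contribute to the number of
#' sequences but to no base count. Frequencies are counts over the total
#' number of sequences, so at a heteroplasmic or gapped site they sum to
#' less than one: out of 100 sequences with 99 A and one A/G heteroplasmy,
#' the site is 99% A and 0% for C, G and T. No renormalisation is applied.
#'
#' @param column Character vector of aligned symbols at one site.
#' @return Named numeric vector `c(A=, C=, G=, T=)` with attribute
#'   `nSequences`.
#' @export
siteFrequencies <- function(column) {
  if (length(column) == 0L) stop("empty alignment column")
  column <- normaliseSymbols(column)
  n <- length(column)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(column == b), numeric(1))
  freqs <- counts / n
  attr(freqs, "nSequences") <- n
  freqs
}

#' Per-site conservation in bits
#'
#' The conservation statistic is 2 minus the Shannon uncertainty of the base
#' frequencies, `Rs = 2 - H` with `H = -sum(p * log2(p))` over bases with
#' positive frequency: 2 bits (log2 of the 4-letter alphabet) at a fully
#' conserved site, 0 at a maximally variable one. With the heteroplasmy rule
#' frequencies may sum to less than one, which can only lower H; the result
#' is clamped to `[0, 2]`.
#'
#' @param freqs Output of [siteFrequencies()] (any numeric vector of base
#'   frequencies works).
#' @param smallSampleCorrection Apply the approximate small-sample bias
#'   correction `e = 3/(2 ln(2) n)` subtracted from Rs (off by default; the
#'   plain statistic is the reported one).
#' @return Conservation in bits, in `[0, 2]`.
#' @export
siteRs <- function(freqs, smallSampleCorrection = FALSE) {
  p <- freqs[freqs > 0]
  H <- if (length(p)) -sum(p * log2(p)) else 0
  rs <- 2 - H
  if (smallSampleCorrection) {
    n <- attr(freqs, "nSequences")
    if (!is.null(n) && n > 0) rs <- rs - 3 / (2 * log(2) * n)
  }
  min(max(rs, 0), 2)
}

#' Conservation track for an alignment
#'
#' Per-site Rs values plus sliding-window identity fractions for the
#' requested window sizes (defaults 101, 401 and 601 bp, the fragment sizes
#' commonly sequenced for the two mitochondrial barcode genes).
#'
#' @param alignment A [GeneAlignment-class].
#' @param windows Integer window sizes; sizes longer than the alignment are
#'   dropped with a warning.
#' @param smallSampleCorrection Passed to [siteRs()].
#' @return List with `rs` (numeric per site) and `windows`, a named list of
#'   data.frames from [slidingWindowIdentity()].
#' @export
conservationTrack <- function(alignment, windows = c(101L, 401L, 601L),
                              smallSampleCorrection = FALSE) {
  stopifnot(is(alignment, "GeneAlignment"))
  m <- alignmentMatrix(alignment)
  rs <- apply(m, 2L, function(col)
    siteRs(siteFrequencies(col), smallSampleCorrection))
  ok <- windows <= length(rs)
  if (!all(ok))
    warning("dropping window size(s) longer than the alignment: ",
            paste(windows[!ok], collapse = ", "))
  wins <- lapply(windows[ok], function(X) slidingWindowIdentity(rs, X))
  names(wins) <- as.character(windows[ok])
  list(rs = rs, windows = wins)
}

#' Sliding-window identity fractions
#'
#' For each window start s (step 1, 1-based), the fraction is the sum of the
#' Rs values across the window divided by `2 * X` (2 being the Rs value of a
#' fully conserved site and X the window size): a 101-bp window that is 100%
#' identical across all sequences scores exactly 1.
#'
#' @param rs Numeric vector of per-site Rs values.
#' @param X Window size, `X <= length(rs)`.
#' @return data.frame with columns `start`, `end`, `fraction`.
#' @export
slidingWindowIdentity <- function(rs, X) {
  n <- length(rs)
  X <- as.integer(X)
  if (X < 1L || X > n) stop("window size must be in [1, length(rs)]")
  cs <- c(0, cumsum(rs))
  starts <- seq_len(n - X + 1L)
  frac <- (cs[starts + X] - cs[starts]) / (2 * X)
  data.frame(start = starts, end = starts + X - 1L, fraction = frac)
}

#' Variable and singleton-variable site counts
#'
#' A site is variable when at least two distinct unambiguous bases occur;
#' it is singleton-variable when exactly two distinct bases occur, the
#' minority base is carried by a single sequence and the majority base by at
#' least two (variation "in a single sample").
#'
#' @param alignment A [GeneAlignment-class] with at least 2 sequences.
#' @return List with `totalVariableSites` and `singletonVariableSites`.
#' @export
variabilityCounts <- function(alignment) {
  stopifnot(is(alignment, "GeneAlignment"), nSequences(alignment) >= 2L)
  m <- alignmentMatrix(alignment)
  stats <- apply(m, 2L, function(col) {
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) sum(col == b), numeric(1))
    counts <- counts[counts > 0]
    variable <- length(counts) >= 2L
    singleton <- length(counts) == 2L &&
      min(counts) == 1L && max(counts) >= 2L
    c(variable, singleton)
  })
  list(totalVariableSites = sum(stats[1L, ]),
       singletonVariableSites = sum(stats[2L, ]))
}

#' Mean conservation as percent of a fully conserved gene
#'
#' `100 * mean(rs) / 2`: 100% when every site is fully conserved.
#'
#' @param rs Numeric vector of per-site Rs values (or the list returned by
#'   [conservationTrack()]).
#' @return Percent in `[0, 100]`.
#' @export
meanConservationPercent <- function(rs) {
  if (is.list(rs)) rs <- rs$rs
  if (!length(rs)) stop("empty conservation track")
  100 * mean(rs) / 2
}

#' Count heteroplasmic (ambiguous) cells in an alignment
#'
#' @param alignment A [GeneAlignment-class].
#' @return Number of cells holding an IUPAC ambiguity symbol (gaps are not
#'   counted).
#' @export
heteroplasmyCount <- function(alignment) {
  m <- alignmentMatrix(alignment)
  sum(!m %in% c("A", "C", "G", "T", "-"))
}
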