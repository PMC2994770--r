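#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet width
NULL

#' GeneAlignment: an aligned set of DNA sequences
#'
#' Wraps a [Biostrings::DNAStringSet] of equal-width sequences with unique
#' sample identifiers. Symbols are normalised on construction: lowercase is
#' raised, `U` becomes `T` and `.` becomes `-`. IUPAC ambiguity codes are
#' retained (the conservation module's heteroplasmy rule needs them).
#'
#' The `siteMap` slot records, for each current column, the 1-based column
#' index in the original alignment. It is the identity for freshly read
#' alignments and is rewritten by [completeDeletion()] so that codon-position
#' masks can still be derived after columns have been dropped.
#'
#' @slot seqs A `DNAStringSet`, all of one width, uniquely named.
#' @slot siteMap Integer vector, one entry per column: original column index.
#' @export
setClass("GeneAlignment",
  slots = c(seqs = "DNAStringSet", siteMap = "integer"))

setValidity("GeneAlignment", function(object) {
  w <- width(object@seqs)
  if (length(w) == 0L) return("alignment has no sequences")
  if (length(unique(w)) != 1L)
    return("aligned sequences must all have the same length")
  ids <- names(object@seqs)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    return("every sequence must carry a sample id")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sample id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@siteMap) != w[1L])
    return("siteMap length must equal the alignment length")
  TRUE
})

#' TaxonomyTable: ranked taxonomic labels per sample
#'
#' Holds one row per sample with subspecies (optional), species, genus,
#' family, order and superorder labels, together with a collapse map sending
#' each sample to its species. Samples of named subspecies of one species
#' collapse to that species, so subspecies pairs count as same-species pairs
#' in discrimination analyses.
#'
#' @slot table A data.frame with columns `sample_id`, `subspecies`,
#'   `species`, `genus`, `family`, `order`, `superorder`.
#' @slot collapseMap Named character vector: sample id -> species.
#' @export
setClass("TaxonomyTable",
  slots = c(table = "data.frame", collapseMap = "character"))

setValidity("TaxonomyTable", function(object) {
  needed <- c("sample_id", "subspecies", "species", "genus", "family",
              "order", "superorder")
  missing <- setdiff(needed, colnames(object@table))
  if (length(missing))
    return(sprintf("missing taxonomy column(s): %s",
                   paste(missing, collapse = ", ")))
  ids <- object@table$sample_id
  if (anyDuplicated(ids))
    return("duplicate sample_id in taxonomy table")
  if (!all(ids %in% names(object@collapseMap)))
    return("collapseMap must cover every sample_id")
  TRUE
})

#' DistanceMatrix: symmetric pairwise distances with metric metadata
#'
#' Distances are stored unscaled (substitutions per site); the x100
#' presentation used in barcoding reports is a formatting flag applied by
#' [distanceValues()] and the writers. Pairs where the Kimura 2-parameter
#' correction is undefined (saturation: the log arguments are non-positive)
#' hold `NA` and are flagged in `saturated`; summaries exclude them and
#' report the exclusion count.
#'
#' @slot values Symmetric numeric matrix with zero diagonal, dimnames =
#'   sample ids. `NA` marks saturated pairs.
#' @slot metric One of `"p"`, `"k2p"`, `"dS"`, `"dN"`.
#' @slot positionSubset One of `"all"`, `"pos1"`, `"pos2"`, `"pos3"`.
#' @slot scaleX100 Logical: present values multiplied by 100.
#' @slot saturated Logical matrix marking pairs with no finite estimate.
#' @export
setClass("DistanceMatrix",
  slots = c(values = "matrix", metric = "character",
            positionSubset = "character", scaleX100 = "logical",
            saturated = "matrix"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("distance matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("distance matrix needs matching row/column sample ids")
  if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE)))
    return("distance matrix must be symmetric")
  if (any(abs(diag(v)) > 1e-12, na.rm = TRUE))
    return("distance matrix diagonal must be zero")
  if (any(v < -1e-12, na.rm = TRUE))
    return("distances must be non-negative")
  if (!object@metric %in% c("p", "k2p", "dS", "dN"))
    return("metric must be one of p, k2p, dS, dN")
  if (!object@positionSubset %in% c("all", "pos1", "pos2", "pos3"))
    return("positionSubset must be one of all, pos1, pos2, pos3")
  if (!identical(dim(object@saturated), dim(v)))
    return("saturated flag matrix must match values in shape")
  TRUE
})

#' ContingencyTable: threshold classification of labelled pairs
#'
#' The two-by-two table of same-species (A) / different-species (a) pairs
#' against below-threshold (B, positive) / at-or-above-threshold (b,
#' negative) K2P (x100) values. Cells follow the barcoding convention:
#' `nAB` true positives, `naB` false positives, `nAb` false negatives,
#' `nab` true negatives. Marginals are derived, never stored.
#'
#' @slot nAB,naB,nAb,nab Numeric cell counts.
#' @slot threshold The K2P (x100) threshold used (`NA` when the table was
#'   built directly from printed counts).
#' @export
setClass("ContingencyTable",
  slots = c(nAB = "numeric", naB = "numeric", nAb = "numeric",
            nab = "numeric", threshold = "numeric"))

setValidity("ContingencyTable", function(object) {
  cells <- c(object@nAB, object@naB, object@nAb, object@nab)
  if (length(cells) != 4L || any(is.na(cells)))
    return("all four cells must be single non-missing counts")
  if (any(cells < 0)) return("cell counts must be non-negative")
  TRUE
})
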