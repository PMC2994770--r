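#' @include AllClasses.R
NULL

#' Sample identifiers
#'
#' @param x A GeneAlignment, TaxonomyTable or DistanceMatrix.
#' @return Character vector of sample ids, in storage order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Number of aligned sites
#'
#' @param x A GeneAlignment.
#' @return Integer site count (bp).
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' Number of sequences
#'
#' @param x A GeneAlignment.
#' @return Integer sequence count.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Alignment as a character matrix
#'
#' One row per sequence, one single-character column per site; rownames are
#' sample ids.
#'
#' @param x A GeneAlignment.
#' @return Character matrix.
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Original column indices of the current alignment columns
#'
#' Identity for freshly constructed alignments; after [completeDeletion()]
#' it maps surviving columns back to their original coordinates so frames
#' and codon masks can be re-derived.
#'
#' @param x A GeneAlignment.
#' @return Integer vector, one entry per current column.
#' @export
setGeneric("siteMap", function(x) standardGeneric("siteMap"))

#' Distance values on the requested scale
#'
#' @param x A DistanceMatrix.
#' @param x100 Present values multiplied by 100 (the barcoding-report
#'   convention). Defaults to the object's own scale flag.
#' @return Numeric matrix (NA where a pair is saturated).
#' @export
setGeneric("distanceValues",
           function(x, x100 = NULL) standardGeneric("distanceValues"))

setMethod("sampleIds", "GeneAlignment", function(x) names(x@seqs))
setMethod("sampleIds", "TaxonomyTable", function(x) x@table$sample_id)
setMethod("sampleIds", "DistanceMatrix", function(x) rownames(x@values))

setMethod("alignmentLength", "GeneAlignment",
          function(x) width(x@seqs)[1L])
setMethod("nSequences", "GeneAlignment", function(x) length(x@seqs))

setMethod("alignmentMatrix", "GeneAlignment", function(x) {
  m <- as.matrix(x@seqs)
  rownames(m) <- names(x@seqs)
  m
})

setMethod("siteMap", "GeneAlignment", function(x) x@siteMap)

setMethod("distanceValues", "DistanceMatrix", function(x, x100 = NULL) {
  if (is.null(x100)) x100 <- x@scaleX100
  if (x100) x@values * 100 else x@values
})

setMethod("show", "GeneAlignment", function(object) {
  cat(sprintf("GeneAlignment: %d sequences x %d sites\n",
              nSequences(object), alignmentLength(object)))
  ids <- sampleIds(object)
  shown <- utils::head(ids, 5L)
  cat("  ids:", paste(shown, collapse = ", "),
      if (length(ids) > 5L) sprintf("... (%d more)", length(ids) - 5L) else "",
      "\n")
  invisible(object)
})

setMethod("show", "TaxonomyTable", function(object) {
  tab <- object@table
  cat(sprintf(
    "TaxonomyTable: %d samples, %d species, %d genera, %d families, %d orders, %d superorders\n",
    nrow(tab), length(unique(tab$species)), length(unique(tab$genus)),
    length(unique(tab$family)), length(unique(tab$order)),
    length(unique(tab$superorder))))
  invisible(object)
})

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@values)
  nsat <- sum(object@saturated[upper.tri(object@saturated)])
  cat(sprintf(
    "DistanceMatrix: %s distance (%s positions), %d samples, %d pairs%s%s\n",
    object@metric, object@positionSubset, n, n * (n - 1L) / 2L,
    if (object@scaleX100) ", x100 scale" else "",
    if (nsat > 0) sprintf(", %d saturated pair(s)", nsat) else ""))
  invisible(object)
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable (threshold %s, K2P x100):\n",
              format(object@threshold)))
  m <- rbind(`< threshold (B)` = c(object@nAB, object@naB),
             `>= threshold (b)` = c(object@nAb, object@nab))
  m <- cbind(m, rowSums(m))
  m <- rbind(m, colSums(m))
  dimnames(m) <- list(c("< threshold (B)", ">= threshold (b)", "total"),
                      c("same species (A)", "different species (a)", "total"))
  print(m)
  invisible(object)
})
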