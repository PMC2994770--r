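#' @include AllClasses.R AllGenerics.R
NULL

IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

normaliseSymbols <- function(x) {
  x <- toupper(x)
  x <- chartr("U.", "T-", x)
  x
}

#' Construct a GeneAlignment
#'
#' @param x A named character vector of aligned sequences or a
#'   `DNAStringSet`. Symbols are normalised (uppercase, `U`->`T`, `.`->`-`);
#'   anything outside the IUPAC DNA alphabet plus `-` is rejected.
#' @param siteMap Optional integer vector mapping current columns to
#'   original coordinates; defaults to the identity.
#' @return A [GeneAlignment-class] object.
#' @examples
#' aln <- GeneAlignment(c(s1 = "ACGTacgT", s2 = "ACGTACGA"))
#' alignmentLength(aln)
#' @export
GeneAlignment <- function(x, siteMap = NULL) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x))
    stop("alignment input must be a named character vector or DNAStringSet")
  x <- normaliseSymbols(x)
  bad <- setdiff(unique(unlist(strsplit(x, ""), use.names = FALSE)), IUPAC_OK)
  if (length(bad))
    stop(sprintf("non-IUPAC symbol(s) in alignment: %s",
                 paste(bad, collapse = ", ")))
  if (length(unique(nchar(x))) != 1L)
    stop("aligned sequences must all have the same length")
  if (is.null(siteMap)) siteMap <- seq_len(nchar(x[1L]))
  new("GeneAlignment", seqs = DNAStringSet(x), siteMap = as.integer(siteMap))
}

#' Read an aligned FASTA file
#'
#' Reads a gapped FASTA alignment (single-line or wrapped). Sequence names
#' are the first whitespace-delimited token of each header. At least two
#' records are required; records must share one length and carry unique ids.
#'
#' @param path Path to the FASTA file.
#' @return A [GeneAlignment-class].
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  # read as raw strings so '.' and 'U' survive until normalisation
  seqs <- as.character(Biostrings::readBStringSet(path))
  if (length(seqs) < 2L)
    stop("an alignment needs at least 2 sequences")
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  GeneAlignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param alignment A [GeneAlignment-class].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(alignment, path, width = 70L) {
  stopifnot(is(alignment, "GeneAlignment"))
  Biostrings::writeXStringSet(alignment@seqs, path, width = width)
  invisible(path)
}

#' Extract a gene from a genome sequence by 1-based inclusive coordinates
#'
#' Coordinates are 1-based and inclusive on both ends, the convention under
#' which human mitochondrial cytochrome b at 14,747..15,887 has length
#' 1,141 bp and COI at 5,904..7,445 has length 1,542 bp.
#'
#' @param genome A character string (or single-sequence `DNAStringSet`
#'   element coerced with `as.character`).
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @return The sub-sequence, length `end - start + 1`.
#' @export
sliceGene <- function(genome, start, end) {
  genome <- as.character(genome)
  stopifnot(length(genome) == 1L)
  if (start < 1L || start > end)
    stop("invalid range: need 1 <= start <= end")
  if (end > nchar(genome))
    stop("range extends past the end of the genome")
  substr(genome, start, end)
}

#' Codon-position mask for an alignment
#'
#' Partitions in-frame sites into first, second and third codon positions.
#' The frame starts at column `frameOffset + 1`; a trailing incomplete codon
#' is excluded from every set.
#'
#' @param alignmentLength Number of sites.
#' @param frameOffset 0, 1 or 2 columns preceding the first complete codon.
#' @return List with integer vectors `pos1`, `pos2`, `pos3` and the
#'   `frameOffset` used.
#' @examples
#' codonMask(7)  # site 7 belongs to no set
#' @export
codonMask <- function(alignmentLength, frameOffset = 0L) {
  stopifnot(alignmentLength >= 3L, frameOffset %in% 0:2)
  k <- (alignmentLength - frameOffset) %/% 3L
  if (k < 1L) stop("no complete codon in frame")
  first <- frameOffset + 1L + 3L * (seq_len(k) - 1L)
  list(pos1 = first, pos2 = first + 1L, pos3 = first + 2L,
       frameOffset = as.integer(frameOffset))
}

#' Codon-position class of each current alignment column
#'
#' Uses the alignment's [siteMap()] so that positions stay anchored to the
#' original coordinates after column removal. Columns before the frame start
#' or in a trailing incomplete codon (judged on the original length) get NA.
#'
#' @param alignment A [GeneAlignment-class].
#' @param frameOffset As in [codonMask()].
#' @return Integer vector in \{1, 2, 3, NA\}, one per current column.
#' @export
sitePositionClasses <- function(alignment, frameOffset = 0L) {
  orig <- siteMap(alignment)
  origLen <- max(orig)
  k <- (origLen - frameOffset) %/% 3L
  cls <- ((orig - 1L - frameOffset) %% 3L) + 1L
  cls[orig <= frameOffset | orig > frameOffset + 3L * k] <- NA_integer_
  cls
}

#' Read a taxonomy table (TSV)
#'
#' Expects a header with columns `sample_id`, `subspecies`, `species`,
#' `genus`, `family`, `order`, `superorder`. An empty subspecies field means
#' the sample is the nominal species. The collapse map sends every sample to
#' its species, so subspecies of one species are treated as that species in
#' downstream same/different-species labelling.
#'
#' @param path Path to the TSV file.
#' @return A [TaxonomyTable-class].
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  TaxonomyTable(tab)
}

#' Construct a TaxonomyTable from a data.frame
#'
#' @param tab data.frame with the seven required columns (see
#'   [readTaxonomy()]).
#' @return A [TaxonomyTable-class].
#' @export
TaxonomyTable <- function(tab) {
  needed <- c("sample_id", "subspecies", "species", "genus", "family",
              "order", "superorder")
  missing <- setdiff(needed, colnames(tab))
  if (length(missing))
    stop(sprintf("missing taxonomy column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in taxonomy table")
  tab$subspecies[is.na(tab$subspecies)] <- ""
  collapse <- stats::setNames(tab$species, tab$sample_id)
  new("TaxonomyTable", table = tab[, needed], collapseMap = collapse)
}

#' Collapsed species label for samples
#'
#' @param taxonomy A [TaxonomyTable-class].
#' @param ids Sample ids to resolve.
#' @return Character vector of species labels.
#' @export
collapseSpecies <- function(taxonomy, ids) {
  stopifnot(is(taxonomy, "TaxonomyTable"))
  unknown <- setdiff(ids, names(taxonomy@collapseMap))
  if (length(unknown))
    stop(sprintf("sample id(s) not in taxonomy: %s",
                 paste(unknown, collapse = ", ")))
  unname(taxonomy@collapseMap[ids])
}

#' Rank labels for samples
#'
#' @param taxonomy A [TaxonomyTable-class].
#' @param ids Sample ids.
#' @param rank One of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"superorder"`.
#' @return Character vector of labels at that rank.
#' @export
rankLabels <- function(taxonomy, ids,
                       rank = c("species", "genus", "family", "order",
                                "superorder")) {
  rank <- match.arg(rank)
  tab <- taxonomy@table
  idx <- match(ids, tab$sample_id)
  if (anyNA(idx))
    stop(sprintf("sample id(s) not in taxonomy: %s",
                 paste(ids[is.na(idx)], collapse = ", ")))
  tab[[rank]][idx]
}

#' Read / write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] and
#' [ape::write.tree()]; a round trip preserves topology, labels and branch
#' lengths to at least six decimals.
#'
#' @param path File path.
#' @return `readNewickTree` returns an [ape::phylo] object.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop(sprintf("could not parse Newick file: %s", path))
  tree
}

#' @rdname readNewickTree
#' @param tree An [ape::phylo] object.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
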