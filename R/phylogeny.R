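#' @include distances.R
NULL

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion,
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j`. Ties are broken deterministically
#' by the lowest (row, column) index of the current matrix. Branch lengths
#' come from the standard two-point formulas; a negative estimate is clamped
#' to zero with the deficit transferred to the sibling edge so the path
#' length between the two joined nodes is preserved. The result is an
#' unrooted [ape::phylo] tree (basal trifurcation).
#'
#' @param dm A [DistanceMatrix-class] or a symmetric numeric matrix with
#'   dimnames; at least 3 taxa, all entries finite.
#' @return An `ape::phylo` object.
#' @export
njTree <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) distanceValues(dm, x100 = FALSE) else
    as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries (saturated pairs?)")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # Each active node carries its newick fragment; lengths are attached on join.
  frag <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    # which.min on the matrix is column-major; scan row-major for the
    # documented lowest-(row, column) tie rule.
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(r - 1L)) {
      j <- which.min(Q[i, ])
      if (Q[i, j] < bestQ) { bestQ <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newD <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newD[keep]),
                c(newD[keep], 0))
    frag <- c(frag[keep], newFrag)
    d <- d2
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1L], fmt(l1), frag[2L], fmt(l2), frag[3L], fmt(l3))
  ape::read.tree(text = newick)
}

# Leaf sets on the child side of every edge (unrooted bipartitions), via a
# single post-order pass.
edgeLeafSets <- function(tree) {
  nTips <- length(tree$tip.label)
  desc <- vector("list", nTips + tree$Nnode)
  for (i in seq_len(nTips)) desc[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(k) desc[[tree$edge[k, 2L]]])
}

#' Largest pure subset of a taxonomic group on a tree
#'
#' The largest subset of `group` that forms one entire side of some edge
#' bipartition containing no non-group leaves. Both orientations of every
#' edge are considered (unrooted semantics), so the result does not depend
#' on where the tree is rooted. A singleton group returns itself; a group
#' spanning all leaves returns the whole group.
#'
#' @param tree An [ape::phylo] tree.
#' @param group Character vector of leaf labels, a subset of the tree's
#'   leaves.
#' @return Character vector: the members of the largest pure bipartition
#'   side.
#' @export
maxPureSubset <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"), length(group) >= 1L)
  tips <- tree$tip.label
  unknown <- setdiff(group, tips)
  if (length(unknown))
    stop(sprintf("leaf label(s) not in tree: %s",
                 paste(unknown, collapse = ", ")))
  groupIdx <- match(group, tips)
  allIdx <- seq_along(tips)
  if (length(groupIdx) == length(tips)) return(group)
  best <- groupIdx[1L]   # any single leaf of the group is a pure side
  for (side in edgeLeafSets(tree)) {
    if (all(side %in% groupIdx) && length(side) > length(best))
      best <- side
    comp <- setdiff(allIdx, side)
    if (all(comp %in% groupIdx) && length(comp) > length(best))
      best <- comp
  }
  tips[sort(best)]
}

#' Tree-versus-taxonomy congruence score
#'
#' For each group at the requested rank, the correctly grouped members are
#' those in the group's largest pure bipartition ([maxPureSubset()]); the
#' group's percentage is `100 * correct / n`. Two accounting variants: with
#' `"per_sample"` every sample is a member; with `"species_collapsed"` the
#' tree is first pruned to one representative per species (the
#' first-listed sample), so a set of conspecific subspecies samples counts
#' once. The overall percentage pools correctly grouped members over all
#' groups.
#'
#' @param tree An [ape::phylo] tree whose leaves resolve in `taxonomy`.
#' @param taxonomy A [TaxonomyTable-class].
#' @param rank `"superorder"`, `"order"`, `"family"`, `"genus"` or
#'   `"species"`.
#' @param variant `"per_sample"` or `"species_collapsed"`.
#' @return List with `rank`, `variant`, `groups` (data.frame `group`, `n`,
#'   `correct`, `percent`) and `overallPercent`.
#' @export
congruence <- function(tree, taxonomy,
                       rank = c("superorder", "order", "family", "genus",
                                "species"),
                       variant = c("per_sample", "species_collapsed")) {
  rank <- match.arg(rank)
  variant <- match.arg(variant)
  stopifnot(inherits(tree, "phylo"), is(taxonomy, "TaxonomyTable"))
  leaves <- tree$tip.label
  species <- collapseSpecies(taxonomy, leaves)   # validates leaf ids
  if (variant == "species_collapsed") {
    keep <- leaves[!duplicated(species)]
    if (length(keep) < length(leaves)) {
      if (length(keep) < 2L)
        stop("fewer than 2 species represented; nothing to score")
      tree <- ape::keep.tip(tree, keep)
      leaves <- tree$tip.label
    }
  }
  labels <- rankLabels(taxonomy, leaves, rank)
  groups <- split(leaves, labels)
  res <- data.frame(
    group = names(groups),
    n = lengths(groups),
    correct = vapply(groups, function(g)
      length(maxPureSubset(tree, g)), numeric(1)),
    row.names = NULL)
  res$percent <- 100 * res$correct / res$n
  list(rank = rank, variant = variant, groups = res,
       overallPercent = 100 * sum(res$correct) / sum(res$n))
}

#' Congruence report across all ranks and both accounting variants
#'
#' @inheritParams congruence
#' @param ranks Ranks to score.
#' @return data.frame with columns `rank`, `variant`, `overallPercent`.
#' @export
congruenceAcrossRanks <- function(tree, taxonomy,
                                  ranks = c("superorder", "order", "family",
                                            "genus")) {
  grid <- expand.grid(rank = ranks,
                      variant = c("per_sample", "species_collapsed"),
                      stringsAsFactors = FALSE)
  grid$overallPercent <- mapply(function(r, v)
    congruence(tree, taxonomy, r, v)$overallPercent,
    grid$rank, grid$variant)
  grid
}
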