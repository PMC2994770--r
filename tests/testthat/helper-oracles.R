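# Independent oracles, deliberately written with explicit loops / recursion,
# kept apart from the package's vectorised / table-driven implementations.

# K2P by an explicit per-site loop tabulating transitions and transversions.
bruteK2P <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  nts <- 0L; ntv <- 0L
  for (i in seq_along(a)) {
    if (a[i] != b[i]) {
      if (purine[[a[i]]] == purine[[b[i]]]) nts <- nts + 1L
      else ntv <- ntv + 1L
    }
  }
  P <- nts / length(a); Q <- ntv / length(a)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Nei-Gojobori pathway counts by recursive depth-first enumeration over all
# step orders, excluding any path visiting a stop codon.
ngPathOracle <- function(c1, c2, code) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  paths <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      nxtCodon <- paste(nxt, collapse = "")
      if (code[[nxtCodon]] == "*") next
      syn <- code[[paste(cur, collapse = "")]] == code[[nxtCodon]]
      recurse(nxt, setdiff(remaining, pos),
              sd + as.integer(syn), nd + as.integer(!syn))
    }
  }
  recurse(a, which(a != b), 0L, 0L)
  if (!length(paths)) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

# AUC as the brute-force Mann-Whitney pair count (smaller value = positive),
# ties counted one half.
bruteAUC <- function(intra, inter) {
  wins <- 0
  for (x in intra) for (y in inter) {
    if (x < y) wins <- wins + 1
    else if (x == y) wins <- wins + 0.5
  }
  wins / (length(intra) * length(inter))
}

# Random binary tree with positive branch lengths and its additive distance
# matrix (path lengths).
randomAdditiveCase <- function(nTaxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.05, 1))
  tree <- ape::unroot(tree)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# Quick alignment builders -------------------------------------------------

alnFromStrings <- function(...) {
  s <- c(...)
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  GeneAlignment(s)
}

# Small taxonomy: one row per sample id, ranks supplied as parallel vectors.
taxFrom <- function(ids, species, genus = species, family = genus,
                    order = family, superorder = order, subspecies = "") {
  TaxonomyTable(data.frame(
    sample_id = ids, subspecies = subspecies, species = species,
    genus = genus, family = family, order = order,
    superorder = superorder, stringsAsFactors = FALSE))
}
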