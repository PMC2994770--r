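#' @include alignment-io.R genetic-code.R
NULL

#' Simulation configuration
#'
#' Defines a balanced ranked taxonomy and the Kimura 2-parameter
#' substitution process used to evolve sequences along it. Defaults emulate
#' the structure of a mammalian two-locus barcoding study: interspecific
#' divergences centred around a K2P (x100) of 25 with intraspecific
#' divergences well below 1.5 (a clear barcoding gap), third-position rates
#' well above first above second, and rare heteroplasmic base calls.
#'
#' `interDepth` is the expected pairwise divergence (substitutions/site)
#' between two species of the same family; divergences at family, order and
#' superorder level are scaled up by `rankDepthFactors`. `intraDepth` is the
#' expected pairwise divergence between two samples of one species.
#' `posRateMultipliers` scale branch lengths per codon-position class; the
#' defaults average 1 so the overall expected divergence stays at the
#' configured depth.
#'
#' @param nSuperorders,ordersPerSuperorder,familiesPerOrder,speciesPerFamily
#'   Balanced taxonomy shape.
#' @param samplesPerSpecies Samples drawn per species.
#' @param seqLength Sites (divisible by 3, at least 300).
#' @param kappa Transition/transversion rate ratio.
#' @param interDepth,intraDepth Expected pairwise divergences
#'   (substitutions/site); `intraDepth < interDepth`.
#' @param rankDepthFactors Named multipliers of `interDepth` for divergences
#'   at `family`, `order` and `superorder` level.
#' @param posRateMultipliers Length-3 positive rate multipliers for 1st,
#'   2nd and 3rd codon positions.
#' @param heteroplasmyRate Per-cell probability of an injected heteroplasmic
#'   (two-base IUPAC) call, in `[0, 0.01]`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(nSuperorders = 2L, ordersPerSuperorder = 2L,
                             familiesPerOrder = 2L, speciesPerFamily = 3L,
                             samplesPerSpecies = 2L, seqLength = 1200L,
                             kappa = 4, interDepth = 0.25,
                             intraDepth = 0.004,
                             rankDepthFactors = c(family = 1.3, order = 1.6,
                                                  superorder = 2.0),
                             posRateMultipliers = c(0.6, 0.2, 2.2),
                             heteroplasmyRate = 1e-5, seed = 1L) {
  cfg <- list(nSuperorders = as.integer(nSuperorders),
              ordersPerSuperorder = as.integer(ordersPerSuperorder),
              familiesPerOrder = as.integer(familiesPerOrder),
              speciesPerFamily = as.integer(speciesPerFamily),
              samplesPerSpecies = as.integer(samplesPerSpecies),
              seqLength = as.integer(seqLength), kappa = kappa,
              interDepth = interDepth, intraDepth = intraDepth,
              rankDepthFactors = rankDepthFactors,
              posRateMultipliers = posRateMultipliers,
              heteroplasmyRate = heteroplasmyRate, seed = as.integer(seed))
  if (cfg$seqLength < 300L || cfg$seqLength %% 3L != 0L)
    stop("seqLength must be >= 300 and divisible by 3")
  if (!(cfg$intraDepth < cfg$interDepth))
    stop("intraDepth must be smaller than interDepth")
  if (any(cfg$posRateMultipliers <= 0) ||
      length(cfg$posRateMultipliers) != 3L)
    stop("posRateMultipliers must be 3 positive values")
  if (cfg$kappa <= 0) stop("kappa must be positive")
  if (cfg$heteroplasmyRate < 0 || cfg$heteroplasmyRate > 0.01)
    stop("heteroplasmyRate must lie in [0, 0.01]")
  f <- cfg$rankDepthFactors
  if (!all(c("family", "order", "superorder") %in% names(f)) ||
      !(1 <= f[["family"]] && f[["family"]] <= f[["order"]] &&
        f[["order"]] <= f[["superorder"]]))
    stop("rankDepthFactors must satisfy 1 <= family <= order <= superorder")
  structure(cfg, class = "simulationConfig")
}

#' Simulate a ranked taxonomy and its species/sample tree
#'
#' Builds a balanced ranked tree in which two samples of one species
#' coalesce at depth `intraDepth/2`, two species of one family at
#' `interDepth/2`, and families / orders / superorders at that depth scaled
#' by `rankDepthFactors`. Genus is taken as one genus per family. True
#' pairwise distances are additive path lengths on the tree. The build is
#' deterministic given the configuration.
#'
#' @param config A [simulationConfig()].
#' @return A list of class `truthBundle`: `taxonomy`
#'   ([TaxonomyTable-class]), `tree` ([ape::phylo] with true branch
#'   lengths), `trueDistances` (additive matrix) and `config`.
#' @export
simulateTaxonomy <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  tSample <- config$intraDepth / 2
  tSpecies <- config$interDepth / 2
  tFamily <- tSpecies * config$rankDepthFactors[["family"]]
  tOrder <- tSpecies * config$rankDepthFactors[["order"]]
  tSuper <- tSpecies * config$rankDepthFactors[["superorder"]]

  rows <- list(); spCounter <- 0L
  # A fragment is a newick substring plus the height of its node above the
  # leaves; joins attach branch lengths of (join height - child height).
  # A rank represented by a single child collapses: the fragment passes
  # through unchanged, keeping every branch length height-consistent.
  joinOrPass <- function(children, height) {
    if (length(children) == 1L) return(children[[1L]])
    parts <- vapply(children, function(ch)
      sprintf("%s:%.10g", ch$str, height - ch$height), character(1))
    list(str = sprintf("(%s)", paste(parts, collapse = ",")), height = height)
  }
  soFrags <- vector("list", config$nSuperorders)
  for (so in seq_len(config$nSuperorders)) {
    soLab <- sprintf("so%d", so)
    ordFrags <- vector("list", config$ordersPerSuperorder)
    for (od in seq_len(config$ordersPerSuperorder)) {
      odLab <- sprintf("ord%d", (so - 1L) * config$ordersPerSuperorder + od)
      famFrags <- vector("list", config$familiesPerOrder)
      for (fa in seq_len(config$familiesPerOrder)) {
        faNum <- ((so - 1L) * config$ordersPerSuperorder + od - 1L) *
          config$familiesPerOrder + fa
        faLab <- sprintf("fam%d", faNum)
        genLab <- sprintf("gen%d", faNum)
        spFrags <- vector("list", config$speciesPerFamily)
        for (sp in seq_len(config$speciesPerFamily)) {
          spCounter <- spCounter + 1L
          spLab <- sprintf("sp%02d", spCounter)
          tipLabs <- sprintf("%s_%d", spLab, seq_len(config$samplesPerSpecies))
          for (tip in tipLabs)
            rows[[tip]] <- data.frame(
              sample_id = tip, subspecies = "", species = spLab,
              genus = genLab, family = faLab, order = odLab,
              superorder = soLab, stringsAsFactors = FALSE)
          spFrags[[sp]] <- joinOrPass(
            lapply(tipLabs, function(t) list(str = t, height = 0)), tSample)
        }
        famFrags[[fa]] <- joinOrPass(spFrags, tSpecies)
      }
      ordFrags[[od]] <- joinOrPass(famFrags, tFamily)
    }
    soFrags[[so]] <- joinOrPass(ordFrags, tOrder)
  }
  root <- joinOrPass(soFrags, tSuper)
  if (!grepl("^\\(", root$str))
    stop("configuration yields fewer than 2 leaves; nothing to simulate")
  tree <- ape::read.tree(text = paste0(root$str, ";"))
  taxonomy <- TaxonomyTable(do.call(rbind, rows))
  trueD <- ape::cophenetic.phylo(tree)
  trueD <- trueD[taxonomy@table$sample_id, taxonomy@table$sample_id]
  structure(list(taxonomy = taxonomy, tree = tree, trueDistances = trueD,
                 config = config),
            class = "truthBundle")
}

# Kimura 2-parameter transition probabilities for branch length t (expected
# substitutions/site with rates normalised to alpha + 2*beta = 1):
#   P(same) = 1/4 + 1/4 e^{-4 beta t} + 1/2 e^{-2(alpha+beta) t}
#   P(transition) = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   P(each transversion) = 1/4 - 1/4 e^{-4 beta t}
k2pBranchProbs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)   # each of the two transversion targets
}

# Evolve integer base codes (A=1 C=2 G=3 T=4) one branch.
evolveBranch <- function(codes, t, kappa, classes, multipliers) {
  out <- codes
  tsPartner <- c(3L, 4L, 1L, 2L)       # A<->G, C<->T
  tvPartners <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
  for (cl in 1:3) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    pr <- k2pBranchProbs(t * multipliers[cl], kappa)
    u <- stats::runif(length(idx))
    stay <- u < pr["same"]
    trans <- !stay & u < pr["same"] + pr["ts"]
    tv <- !(stay | trans)
    cur <- codes[idx]
    newc <- cur
    newc[trans] <- tsPartner[cur[trans]]
    if (any(tv)) {
      pick <- stats::runif(sum(tv)) < 0.5
      tvTargets <- t(vapply(cur[tv], function(b) tvPartners[[b]], integer(2)))
      newc[tv] <- ifelse(pick, tvTargets[, 1L], tvTargets[, 2L])
    }
    out[idx] <- newc
  }
  out
}

#' Evolve an alignment along the true tree
#'
#' Sequences evolve site-independently under the Kimura 2-parameter process
#' (transition/transversion ratio `kappa`) using the exact branch transition
#' probabilities, so the expected divergence equals the additive path length
#' (times the codon-position rate multiplier for each position class). The
#' root sequence is drawn uniformly over stop-free codons of the vertebrate
#' mitochondrial code, so the root carries no in-frame stop. Deterministic
#' given the seed.
#'
#' @param bundle A `truthBundle` from [simulateTaxonomy()].
#' @param seed Integer seed (defaults to the bundle's configured seed).
#' @return A [GeneAlignment-class] with one sequence per tree leaf.
#' @export
evolveAlignment <- function(bundle, seed = bundle$config$seed) {
  stopifnot(inherits(bundle, "truthBundle"))
  config <- bundle$config
  set.seed(as.integer(seed))
  tabs <- ngTables()
  L <- config$seqLength
  nCodons <- L %/% 3L
  classes <- rep(1:3, nCodons)
  mult <- config$posRateMultipliers

  senseCodons <- which(!tabs$isStop)
  rootCodons <- sample(senseCodons, nCodons, replace = TRUE)
  rootSeq <- match(unlist(strsplit(paste(codonString(rootCodons),
                                         collapse = ""), ""),
                          use.names = FALSE), NG_BASES)

  tree <- bundle$tree
  nTips <- length(tree$tip.label)
  seqAt <- vector("list", nTips + tree$Nnode)
  root <- nTips + 1L
  seqAt[[root]] <- rootSeq
  ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    seqAt[[child]] <- evolveBranch(seqAt[[parent]], ord$edge.length[k],
                                   config$kappa, classes, mult)
  }
  seqs <- vapply(seq_len(nTips), function(i)
    paste(NG_BASES[seqAt[[i]]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  # keep taxonomy row order for convenience
  GeneAlignment(seqs[bundle$taxonomy@table$sample_id])
}

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Inject heteroplasmic base calls into an alignment
#'
#' Randomly chosen (sequence, site) cells holding an unambiguous base are
#' replaced by the two-base IUPAC code joining the current base with one
#' random alternative, emulating heteroplasmic positions in mitochondrial
#' sequence data. Deterministic given the seed.
#'
#' @param alignment A [GeneAlignment-class].
#' @param rate Per-cell injection probability, in `[0, 0.01]`.
#' @param seed Integer seed.
#' @return A [GeneAlignment-class]; the number of injected cells is
#'   attached as attribute `nInjected`.
#' @export
injectHeteroplasmy <- function(alignment, rate, seed) {
  stopifnot(is(alignment, "GeneAlignment"))
  if (rate < 0 || rate > 0.01)
    stop("heteroplasmy rate must lie in [0, 0.01]")
  set.seed(as.integer(seed))
  m <- alignmentMatrix(alignment)
  eligible <- which(m %in% c("A", "C", "G", "T"))
  hits <- eligible[stats::runif(length(eligible)) < rate]
  for (cell in hits) {
    base <- m[cell]
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    key <- paste(sort(c(base, alt)), collapse = "")
    m[cell] <- IUPAC_PAIR[[key]]
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  out <- GeneAlignment(seqs, siteMap = siteMap(alignment))
  attr(out, "nInjected") <- length(hits)
  out
}

#' Simulate a complete locus: taxonomy, truth and alignment
#'
#' Convenience wrapper chaining [simulateTaxonomy()], [evolveAlignment()]
#' and [injectHeteroplasmy()] (at the configured rate).
#'
#' @param config A [simulationConfig()].
#' @return List with `alignment`, `taxonomy`, `truth` (the bundle) and
#'   `nHeteroplasmic`.
#' @export
simulateLocus <- function(config) {
  bundle <- simulateTaxonomy(config)
  aln <- evolveAlignment(bundle)
  nh <- 0L
  if (config$heteroplasmyRate > 0) {
    aln <- injectHeteroplasmy(aln, config$heteroplasmyRate,
                              seed = config$seed + 1L)
    nh <- attr(aln, "nInjected")
  }
  list(alignment = aln, taxonomy = bundle$taxonomy, truth = bundle,
       nHeteroplasmic = nh)
}
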