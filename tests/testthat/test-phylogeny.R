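test_that("NJ recovers a known 4-taxon additive tree exactly", {
  # ((A:1,B:2):1,(C:3,D:4):1) as path-length matrix
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 6
  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 7
  d["B", "D"] <- d["D", "B"] <- 8
  d["C", "D"] <- d["D", "C"] <- 7
  tree <- njTree(d)
  expect_s3_class(tree, "phylo")
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-9)
  # branch lengths: tips A and B at 1 and 2
  expect_equal(tree$edge.length[tree$edge[, 2] ==
                                  which(tree$tip.label == "A")], 1,
               tolerance = 1e-9)
  expect_equal(tree$edge.length[tree$edge[, 2] ==
                                  which(tree$tip.label == "B")], 2,
               tolerance = 1e-9)
})

test_that("3-taxon trees use the closed three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- njTree(d)
  expect_equal(sort(tree$edge.length), sort(c(0.5, 1.5, 2.5)))
  expect_equal(ape::cophenetic.phylo(tree)[c("a", "b", "c"),
                                           c("a", "b", "c")], d,
               tolerance = 1e-9)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- NA
  expect_error(njTree(d), "non-finite")
})

test_that("NJ recovers random additive topologies (quartet oracle: ape)", {
  skip_if_not_installed("phangorn")
  for (seed in 1:12) {
    n <- 4L + (seed %% 5L)
    case <- randomAdditiveCase(n, seed)
    got <- njTree(case$d)
    expect_equal(as.numeric(phangorn::RF.dist(got, case$tree)), 0)
    # independent oracle: ape's own NJ must agree on topology too
    expect_equal(as.numeric(phangorn::RF.dist(got, ape::nj(case$d))), 0)
    # additive matrix is reproduced by the reconstructed tree
    expect_equal(ape::cophenetic.phylo(got)[rownames(case$d),
                                            colnames(case$d)],
                 case$d, tolerance = 1e-8)
  }
})

test_that("NJ tie-breaking is deterministic on ultrametric input", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- njTree(d)
  t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("max pure subset finds the largest uncontaminated bipartition", {
  tree <- ape::read.tree(text = "((a1,a2),((a3,b1),(b2,b3)));")
  expect_setequal(maxPureSubset(tree, c("a1", "a2", "a3")), c("a1", "a2"))
  expect_setequal(maxPureSubset(tree, c("b1", "b2", "b3")), c("b2", "b3"))
  expect_setequal(maxPureSubset(tree, tree$tip.label), tree$tip.label)
  expect_equal(maxPureSubset(tree, "a3"), "a3")   # singleton convention
  expect_error(maxPureSubset(tree, "zz"), "not in tree")
  # monophyletic group comes back whole
  mono <- ape::read.tree(text = "(((a1,a2),a3),(b1,(b2,b3)));")
  expect_setequal(maxPureSubset(mono, c("a1", "a2", "a3")),
                  c("a1", "a2", "a3"))
})

test_that("max pure subset uses unrooted semantics: re-rooting is harmless", {
  tree <- ape::read.tree(text = "((a1,a2),((a3,b1),(b2,b3)));")
  for (out in c("a1", "b2", "a3")) {
    rr <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    expect_setequal(maxPureSubset(rr, c("b2", "b3")), c("b2", "b3"))
    expect_setequal(maxPureSubset(rr, c("a1", "a2")), c("a1", "a2"))
  }
})

test_that("congruence scores per rank with both accounting variants", {
  # 24-member synthetic order with 4 members grafted away from the main
  # clade; a third order keeps the displaced block from being rescued by
  # the complement side of a bipartition (unrooted semantics).
  inA <- paste0("a", 1:20)
  outA <- paste0("a", 21:24)
  zs <- paste0("z", 1:6)
  ws <- paste0("w", 1:2)
  nw <- sprintf("((%s),((%s),(%s)),(%s));",
                paste(inA, collapse = ","), paste(outA, collapse = ","),
                paste(zs, collapse = ","), paste(ws, collapse = ","))
  tree <- ape::read.tree(text = nw)
  tax <- taxFrom(c(inA, outA, zs, ws),
                 species = c(inA, outA, zs, ws),
                 order = rep(c("OrdA", "OrdZ", "OrdW"), c(24, 6, 2)))
  rep <- congruence(tree, tax, "order", "per_sample")
  a <- rep$groups[rep$groups$group == "OrdA", ]
  expect_equal(a$correct, 20)
  expect_equal(a$percent, 100 * 20 / 24, tolerance = 1e-9)
  expect_equal(rep$overallPercent, 100 * 28 / 32, tolerance = 1e-9)
})

test_that("conspecific samples count once under species collapsing", {
  # five subspecies samples of one species forming a clade
  ursus <- paste0("u", 1:5)
  others <- paste0("v", 1:3)
  tree <- ape::read.tree(text = sprintf("((%s),(%s));",
                                        paste(ursus, collapse = ","),
                                        paste(others, collapse = ",")))
  tax <- taxFrom(c(ursus, others),
                 species = c(rep("Ursus thibetanus", 5), others),
                 genus = rep(c("Ursus", "Vulpes"), c(5, 3)),
                 family = rep(c("Ursidae", "Canidae"), c(5, 3)),
                 order = "Carnivora", superorder = "Laurasiatheria")
  per <- congruence(tree, tax, "genus", "per_sample")
  col <- congruence(tree, tax, "genus", "species_collapsed")
  expect_equal(per$groups$n[per$groups$group == "Ursus"], 5L)
  expect_equal(col$groups$n[col$groups$group == "Ursus"], 1L)
  expect_equal(per$overallPercent, 100)
  expect_equal(col$overallPercent, 100)
})

test_that("congruence is invariant to leaves outside every scored group", {
  tree <- ape::read.tree(text = "(((a1,a2),(b1,b2)),extra);")
  tax <- taxFrom(c("a1", "a2", "b1", "b2", "extra"),
                 species = c("a1", "a2", "b1", "b2", "extra"),
                 family = c("A", "A", "B", "B", "X"))
  with <- congruence(tree, tax, "family", "per_sample")
  pruned <- ape::drop.tip(tree, "extra")
  without <- congruence(pruned, tax, "family", "per_sample")
  keep <- with$groups$group %in% c("A", "B")
  expect_equal(with$groups[keep, ], without$groups[without$groups$group
                                                   %in% c("A", "B"), ])
})
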