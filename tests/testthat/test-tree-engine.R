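twoLeaf <- ape::read.tree(text = "(a,b);")
threeLeaf <- ape::read.tree(text = "((a,b),c);")

test_that("a two-leaf tree scores the pairwise distance", {
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  seqs <- c(a = "ACGT", b = "AGT")
  fit <- doTraversal(twoLeaf, seqs, m)
  expect_equal(traversalCost(fit), editCost("ACGT", "AGT", m))
  ma <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  fita <- affineDoTraversal(twoLeaf, seqs, ma)
  expect_equal(traversalCost(fita), gotohCost("ACGT", "AGT", ma))
})

test_that("identical leaves give zero cost and identical labels", {
  m <- costModel()
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  seqs <- setNames(rep("ACGTAC", 4), c("a", "b", "c", "d"))
  fit <- doTraversal(tr, seqs, m)
  expect_equal(traversalCost(fit), 0)
  lab <- backtrackAssignment(fit)
  expect_true(all(lab == "ACGTAC"))
  expect_equal(evaluateLabeling(tr, lab, m, "nonaffine"), 0)
})

test_that("unlabeled leaves and non-binary trees are rejected", {
  m <- costModel()
  expect_error(doTraversal(threeLeaf, c(a = "A", b = "C"), m), "leaf")
  star <- ape::read.tree(text = "(a,b,c);")
  expect_error(doTraversal(star, c(a = "A", b = "C", c = "G"), m), "binary")
})

test_that("non-affine backtrack labeling realizes the DO cost (Theorem 1)", {
  set.seed(31)
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  for (r in 1:25) {
    tr <- randomTree(sample(3:8, 1), 0.2)
    sim <- evolveSequences(tr, rootLength = 25, substRate = 1,
                           indelRate = 0.1, maxGap = 3)
    fit <- doTraversal(tr, sim$leaf, m)
    lab <- backtrackAssignment(fit)
    expect_equal(lab[tr$tip.label], sim$leaf)   # compatibility
    expect_equal(evaluateLabeling(tr, lab, m, "nonaffine"),
                 traversalCost(fit))
  }
})

test_that("affine backtrack labeling never exceeds the Affine-DO cost", {
  set.seed(32)
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  for (r in 1:25) {
    tr <- randomTree(sample(3:8, 1), 0.2)
    sim <- evolveSequences(tr, rootLength = 25, substRate = 1,
                           indelRate = 0.1, maxGap = 3)
    fit <- affineDoTraversal(tr, sim$leaf, m)
    lab <- backtrackAssignment(fit)
    expect_lte(evaluateLabeling(tr, lab, m, "affine"),
               traversalCost(fit) + 1e-9)
  }
})

test_that("every rooting of a 3-leaf star yields a valid upper bound", {
  # DO is root-dependent (the median is built from the cherry pair), so
  # rootings may score differently; each must bound the exact optimum
  set.seed(33)
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  star <- ape::read.tree(text = "(a,b,c);")
  for (r in 1:12) {
    seqs <- c(a = randomSeq(sample(4:10, 1)), b = randomSeq(sample(4:10, 1)),
              c = randomSeq(sample(4:10, 1)))
    ex <- exactThreeAlignment(seqs[1], seqs[2], seqs[3], m,
                              median = FALSE)$cost
    for (e in seq_len(nrow(star$edge))) {
      rooted <- rootTree(star, e)
      expect_setequal(rooted$tip.label, star$tip.label)
      expect_gte(traversalCost(doTraversal(rooted, seqs, m)), ex - 1e-9)
    }
  }
})

test_that("rooting preserves leaves and already-rooted trees pass through", {
  star <- ape::read.tree(text = "(a,b,c);")
  rooted <- rootTree(star, 2)
  expect_setequal(rooted$tip.label, star$tip.label)
  expect_equal(rooted$Nnode, 2L)
  expect_identical(rootTree(threeLeaf), threeLeaf)
})

test_that("evaluateLabeling demands a complete labeling", {
  m <- costModel()
  expect_error(evaluateLabeling(twoLeaf, c(a = "A", b = "C"), m,
                                "nonaffine"),
               "missing")
})

test_that("traversal runtime grows roughly quadratically in length", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  set.seed(34)
  mk <- function(n) setNames(replicate(4, randomSeq(n)), c("a", "b", "c", "d"))
  t1 <- system.time(affineDoTraversal(tr, mk(120), m))[["elapsed"]]
  t2 <- system.time(affineDoTraversal(tr, mk(480), m))[["elapsed"]]
  # 4x the length: ~16x the work; allow generous slack but rule out cubic
  expect_lt(t2, max(t1, 0.02) * 80)
})
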