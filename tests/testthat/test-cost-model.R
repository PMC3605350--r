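test_that("set distance matches exhaustive enumeration over the DNA powerset", {
  m <- costModel(subst = 1, gapOpen = 0, gapExtend = 1)
  sym <- c(alphabet(m), indelSymbol(m))
  d <- substCosts(m)
  subsets <- lapply(1:31, function(mask) sym[bitwAnd(mask, 2^(0:4)) != 0])
  for (x in subsets) for (y in subsets) {
    expected <- min(d[x, y, drop = FALSE])
    expect_equal(setDistance(x, y, m), expected)
    w <- witnessPair(x, y, m)
    expect_true(w[1] %in% x && w[2] %in% y)
    expect_equal(d[w[1], w[2]], expected, ignore_attr = TRUE)
  }
})

test_that("set distance is symmetric and reduces to d on singletons", {
  m <- costModel(subst = 3, gapOpen = 2, gapExtend = 2)
  expect_equal(setDistance("A", "G", m), 3)
  expect_equal(setDistance("A", "A", m), 0)
  expect_equal(setDistance("A", "-", m), 2)
  expect_equal(setDistance(c("A", "C"), c("T", "-"), m),
               setDistance(c("T", "-"), c("A", "C"), m))
  # worked examples
  expect_equal(setDistance("A", c("T", "-"), costModel()), 1)
  expect_equal(witnessPair(c("A", "C"), c("C", "G"), costModel()),
               c("C", "C"))
})

test_that("witness pair prefers the indel when it is strictly closer", {
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  expect_equal(witnessPair("A", c("T", "-"), m), c("A", "-"))
})

test_that("decimal costs are carried exactly through integer scaling", {
  sym <- c("A", "C", "G", "T", "-")
  costs <- matrix(1.25, 5, 5, dimnames = list(sym, sym))
  diag(costs) <- 0
  costs[5, ] <- 0.25
  costs[, 5] <- 0.25
  costs[5, 5] <- 0
  m <- costModel(costs = costs, gapOpen = 3.75)
  expect_equal(gapExtend(m), 0.25)
  # C->G directly costs 1.25; deleting and reinserting costs 2 * 0.25
  expect_equal(editCost("AC", "AG", m), 0.5)
  expect_equal(gotohCost("ATTA", "ATTTA", m), 3.75 + 0.25)
  expect_equal(setDistance(c("A", "C"), "G", m), 1.25)
})

test_that("models violating the uniform indel-cost assumption are rejected", {
  sym <- c("A", "C", "G", "T", "-")
  costs <- matrix(1, 5, 5, dimnames = list(sym, sym))
  diag(costs) <- 0
  costs[5, 1] <- costs[1, 5] <- 2   # d(A, indel) differs from the others
  expect_error(costModel(costs = costs), "gap extension")
  asym <- matrix(1, 5, 5, dimnames = list(sym, sym))
  diag(asym) <- 0
  asym[1, 2] <- 3
  expect_error(costModel(costs = asym), "symmetric")
})

test_that("cost matrix TSV round-trips through readCostMatrix", {
  m0 <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  path <- tempfile(fileext = ".tsv")
  tab <- substCosts(m0)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m1 <- readCostMatrix(path, gapOpen = 3)
  expect_equal(substCosts(m1), substCosts(m0))
  expect_equal(gapOpen(m1), 3)
  expect_equal(gapExtend(m1), 1)
})

test_that("powerset tables exist for DNA and are skipped above the cap", {
  m <- costModel()
  expect_equal(dim(m@tables$dp), c(31, 31))
  big <- costModel(alphabet = LETTERS[1:10], subst = 1)
  expect_length(big@tables, 0)
  # on-the-fly fallback still answers set queries
  expect_equal(setDistance(c("A", "B"), c("B", "C"), big), 0)
  expect_error(editDistanceRag(ragFromSequence("AB", big),
                               ragFromSequence("BC", big), big),
               "table")
})
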