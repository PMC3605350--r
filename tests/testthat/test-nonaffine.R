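test_that("RAG edit distance reduces to Needleman-Wunsch on singletons", {
  set.seed(11)
  for (r in 1:60) {
    m <- costModel(subst = sample(1:4, 1), gapOpen = 0,
                   gapExtend = sample(1:3, 1))
    s1 <- randomSeq(sample(0:15, 1))
    s2 <- randomSeq(sample(0:15, 1))
    al <- editDistanceRag(ragFromSequence(s1, m), ragFromSequence(s2, m), m)
    expect_equal(alignmentCost(al), oracleNW(s1, s2, m))
    expect_equal(alignmentCost(al), editCost(s1, s2, m))
  }
})

test_that("base cases: alignment against the empty RAG sums indel costs", {
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  A <- ragFromSequence("ACGT", m)
  E <- rag(list(), m)
  expect_equal(alignmentCost(editDistanceRag(A, E, m)), 4)
  expect_equal(alignmentCost(editDistanceRag(E, E, m)), 0)
  expect_equal(alignmentCost(editDistanceRag(ragFromSequence("AAA", m),
                                             ragFromSequence("AAA", m), m)), 0)
})

test_that("cost is symmetric in the two RAGs", {
  set.seed(12)
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  for (r in 1:30) {
    A <- randomRag(sample(0:6, 1), m)
    B <- randomRag(sample(0:6, 1), m)
    expect_equal(alignmentCost(editDistanceRag(A, B, m)),
                 alignmentCost(editDistanceRag(B, A, m)))
  }
})

test_that("RAG distance equals the closest contained pair (Lemma 1 oracle)", {
  set.seed(13)
  tested <- 0
  while (tested < 80) {
    m <- costModel(subst = sample(1:3, 1), gapOpen = 0,
                   gapExtend = sample(1:2, 1))
    A <- randomRag(sample(0:5, 1), m)
    B <- randomRag(sample(0:5, 1), m)
    if (selectionCount(A) > 64 || selectionCount(B) > 64) next
    tested <- tested + 1
    al <- editDistanceRag(A, B, m)
    expect_equal(alignmentCost(al),
                 bruteClosestPair(A, B, m, affine = FALSE))
    pr <- extractClosestPair(al, m)
    expect_true(pr[1] %in% containedSequences(A))
    expect_true(pr[2] %in% containedSequences(B))
    expect_equal(oracleNW(pr[1], pr[2], m), alignmentCost(al))
  }
})

test_that("the worked RAG aligned to itself has a zero-distance pair", {
  m <- costModel()
  A <- rag(list("A", c("T", "-"), c("T", "-"), c("G", "C")), m)
  al <- editDistanceRag(A, A, m)
  expect_equal(alignmentCost(al), 0)
  pr <- extractClosestPair(al, m)
  expect_equal(pr[1], pr[2])
})

test_that("median columns are the minimal-pair participants", {
  m <- costModel()
  al <- editDistanceRag(rag(list(c("A", "C")), m), rag(list(c("C", "G")), m), m)
  expect_equal(ragToString(medianNonaffine(al, m)), "[C]")
  al2 <- editDistanceRag(ragFromSequence("A", m), ragFromSequence("A", m), m)
  expect_equal(ragToString(medianNonaffine(al2, m)), "[A]")
})

test_that("every median sequence splits the pair distance exactly (Lemma 2)", {
  set.seed(14)
  tested <- 0
  while (tested < 40) {
    m <- costModel(subst = sample(1:2, 1), gapOpen = 0, gapExtend = 1)
    A <- randomRag(sample(1:4, 1), m)
    B <- randomRag(sample(1:4, 1), m)
    if (selectionCount(A) > 16 || selectionCount(B) > 16) next
    al <- editDistanceRag(A, B, m)
    M <- medianNonaffine(al, m)
    if (selectionCount(M) > 64) next
    tested <- tested + 1
    ca <- containedSequences(A)
    cb <- containedSequences(B)
    for (X in containedSequences(M)) {
      mY <- min(vapply(ca, function(y) oracleNW(X, y, m), numeric(1)))
      mZ <- min(vapply(cb, function(z) oracleNW(X, z, m), numeric(1)))
      expect_equal(mY + mZ, alignmentCost(al))
    }
  }
})
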