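test_that("accessory cost functions return the stated case values", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  A <- rag(list(c("T", "-"), "T", c("A", "-"), c("A", "C")), m)
  B <- rag(list("C", c("C", "-"), "-"), m)
  ac <- accessoryCosts(A, B, 2, 1, m)
  expect_equal(ac$geA, 1)            # no indel in {T}
  expect_equal(ac$geB, 1)            # no indel in {C}
  expect_equal(accessoryCosts(A, B, 1, 2, m)$geA, 0)   # indel in {T,-}
  # diag: 0 only when both sets hold an indel
  expect_equal(accessoryCosts(A, B, 1, 2, m)$diag, 0)
  expect_equal(accessoryCosts(A, B, 2, 2, m)$diag, Inf)
  # go: free opening at position 1 with an indel, or at a block start
  expect_equal(accessoryCosts(A, B, 1, 1, m)$goA, 0)   # i=1, indel in A_1
  expect_equal(accessoryCosts(A, B, 3, 1, m)$goA, 0)   # indel enters at i=3
  expect_equal(accessoryCosts(A, B, 2, 1, m)$goA, 3)   # otherwise a
  expect_equal(accessoryCosts(A, B, 1, 3, m)$goB, 3)   # indel in B_2 and B_3
  # subst ignores indels; both-pure-indel comparison is impossible
  expect_equal(accessoryCosts(A, B, 1, 2, m)$subst, 2)
  expect_equal(accessoryCosts(A, B, 4, 1, m)$subst, 0)
  expect_equal(accessoryCosts(A, B, 1, 3, m)$subst, Inf)
  # go' adds the opening when the first set carries an indel
  expect_equal(accessoryCosts(A, B, 1, 2, m)$goPrimeAB, 5)
  expect_equal(accessoryCosts(A, B, 2, 1, m)$goPrimeAB, 2)
})

test_that("affine RAG distance equals textbook Gotoh on singleton RAGs", {
  set.seed(21)
  for (r in 1:120) {
    m <- costModel(subst = sample(1:4, 1), gapOpen = sample(0:7, 1),
                   gapExtend = sample(1:3, 1))
    s1 <- randomSeq(sample(0:18, 1))
    s2 <- randomSeq(sample(0:18, 1))
    al <- affineDistanceRag(ragFromSequence(s1, m), ragFromSequence(s2, m), m)
    expect_equal(alignmentCost(al), oracleGotoh(s1, s2, m))
    expect_equal(gotohCost(s1, s2, m), oracleGotoh(s1, s2, m))
  }
})

test_that("one insertion costs the gap function G(1) = a + b", {
  m <- costModel(gapOpen = 7, gapExtend = 1)
  expect_equal(gotohCost("ATTA", "ATTTA", m), 8)
  expect_equal(gotohCost("ATTA", "ATTA", m), 0)
  A <- ragFromSequence("ACGTT", m)
  expect_equal(alignmentCost(affineDistanceRag(A, rag(list(), m), m)),
               7 + 5)
  expect_equal(alignmentCost(affineDistanceRag(rag(list(), m),
                                               rag(list(), m), m)), 0)
})

test_that("DP matrices satisfy the implemented base cases", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  A <- ragFromSequence("AC", m)
  B <- rag(list("G", c("T", "-")), m)
  al <- affineDistanceRag(A, B, m, keepMatrices = TRUE)
  g <- al@matrices$g; d <- al@matrices$d
  v <- al@matrices$v; h <- al@matrices$h
  expect_equal(g[1, 1], 0)
  expect_equal(d[1, 1], Inf)
  expect_equal(v[1, 1], Inf)
  expect_equal(h[1, 1], Inf)
  # first column: gap in B opened from g, extended at ge(A_i) = b
  expect_equal(v[2, 1], 3 + 1)
  expect_equal(v[3, 1], 3 + 2)
  # first row: gap in A; B_2 holds an indel so its extension is free
  expect_equal(h[1, 2], 3 + 1)
  expect_equal(h[1, 3], 3 + 1)
  # invisible consumption keeps g alive along the first row
  expect_equal(g[1, 2], Inf)        # B_1 = {G} cannot be skipped
  expect_equal(d[2, 1], Inf)
  expect_equal(min(g[3, 3], d[3, 3], v[3, 3], h[3, 3]), alignmentCost(al))
})

test_that("zero gap opening reduces the affine optimum to the edit distance", {
  set.seed(22)
  m <- costModel(subst = 2, gapOpen = 0, gapExtend = 1)
  for (r in 1:60) {
    A <- randomRag(sample(0:8, 1), m)
    B <- randomRag(sample(0:8, 1), m)
    expect_equal(alignmentCost(affineDistanceRag(A, B, m)),
                 alignmentCost(editDistanceRag(A, B, m)))
  }
})

test_that("affine cost is symmetric and equals the closest contained pair", {
  set.seed(23)
  tested <- 0
  while (tested < 60) {
    m <- costModel(subst = sample(1:3, 1), gapOpen = sample(1:5, 1),
                   gapExtend = sample(1:3, 1))
    A <- randomRag(sample(0:5, 1), m)
    B <- randomRag(sample(0:5, 1), m)
    if (selectionCount(A) > 32 || selectionCount(B) > 32) next
    tested <- tested + 1
    al <- affineDistanceRag(A, B, m)
    expect_equal(alignmentCost(al),
                 alignmentCost(affineDistanceRag(B, A, m)))
    expect_equal(alignmentCost(al),
                 bruteClosestPair(A, B, m, affine = TRUE))
  }
})

test_that("the extracted pair attains the affine bound (Theorem 2)", {
  set.seed(24)
  tested <- 0
  while (tested < 120) {
    m <- costModel(subst = sample(1:4, 1), gapOpen = sample(0:7, 1),
                   gapExtend = sample(1:3, 1))
    A <- randomRag(sample(0:6, 1), m)
    B <- randomRag(sample(0:6, 1), m)
    tested <- tested + 1
    al <- affineDistanceRag(A, B, m)
    pr <- extractClosestPairAffine(al, m)
    expect_lte(oracleGotoh(pr[1], pr[2], m), alignmentCost(al) + 1e-9)
  }
})

test_that("affine median of two identical sequences is that sequence", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  al <- affineDistanceRag(ragFromSequence("ACGT", m),
                          ragFromSequence("ACGT", m), m)
  expect_equal(ragToString(medianAffine(al, m)), "[A][C][G][T]")
})

test_that("a single gapped residue becomes an optional median column", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  al <- affineDistanceRag(ragFromSequence("AT", m),
                          ragFromSequence("ACT", m), m)
  M <- medianAffine(al, m)
  expect_equal(ragToString(M), "[A][C-][T]")
  expect_equal(ragGroups(M), c(0L, 0L, 0L))
  expect_setequal(containedSequences(M), c("AT", "ACT"))
})

test_that("multi-column gap blocks become atomic optional groups", {
  m <- costModel(subst = 2, gapOpen = 3, gapExtend = 1)
  al <- affineDistanceRag(ragFromSequence("AT", m),
                          ragFromSequence("ACGGT", m), m)
  M <- medianAffine(al, m)
  expect_equal(ragToString(M), "[A][C-][G-][G-][T]")
  expect_equal(ragGroups(M), c(0L, 1L, 1L, 1L, 0L))
  expect_setequal(containedSequences(M), c("AT", "ACGGT"))
})

test_that("every affine median selection respects the pair bound", {
  set.seed(25)
  tested <- 0
  while (tested < 50) {
    m <- costModel(subst = sample(1:4, 1), gapOpen = sample(1:5, 1),
                   gapExtend = sample(1:3, 1))
    A <- randomRag(sample(1:5, 1), m)
    B <- randomRag(sample(1:5, 1), m)
    if (selectionCount(A) > 16 || selectionCount(B) > 16) next
    al <- affineDistanceRag(A, B, m)
    M <- medianAffine(al, m)
    if (selectionCount(M) > 64) next
    tested <- tested + 1
    ca <- containedSequences(A)
    cb <- containedSequences(B)
    for (X in containedSequences(M)) {
      mY <- min(vapply(ca, function(y) oracleGotoh(X, y, m), numeric(1)))
      mZ <- min(vapply(cb, function(z) oracleGotoh(X, z, m), numeric(1)))
      expect_lte(mY + mZ, alignmentCost(al) + 1e-9)
    }
  }
})
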