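# Independent reference implementations and generators used as oracles.
# These are deliberately written in plain R, separate from the package's
# C++ kernels.

DNA <- c("A", "C", "G", "T")

randomSeq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random RAG with occasional multi-member and indel-bearing columns
randomRag <- function(len, model, pIndel = 0.4, pMulti = 0.25) {
  if (len == 0) return(rag(list(), model))
  cols <- lapply(seq_len(len), function(i) {
    s <- sample(DNA, if (runif(1) < pMulti) 2 else 1)
    if (runif(1) < pIndel) s <- c(s, "-")
    s
  })
  rag(cols, model)
}

# plain Needleman-Wunsch over the model's cost matrix
oracleNW <- function(s1, s2, model) {
  d <- substCosts(model)
  a1 <- strsplit(s1, "")[[1]]
  a2 <- strsplit(s2, "")[[1]]
  n <- length(a1); m <- length(a2)
  C <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) C[i + 1, 1] <- C[i, 1] + d[a1[i], "-"]
  for (j in seq_len(m)) C[1, j + 1] <- C[1, j] + d[a2[j], "-"]
  for (i in seq_len(n)) for (j in seq_len(m))
    C[i + 1, j + 1] <- min(C[i, j] + d[a1[i], a2[j]],
                           C[i, j + 1] + d[a1[i], "-"],
                           C[i + 1, j] + d[a2[j], "-"])
  C[n + 1, m + 1]
}

# textbook three-matrix Gotoh with gap cost G(k) = a + b k,
# gap-to-gap transitions allowed
oracleGotoh <- function(s1, s2, model) {
  d <- substCosts(model)
  a <- gapOpen(model); b <- gapExtend(model)
  a1 <- strsplit(s1, "")[[1]]
  a2 <- strsplit(s2, "")[[1]]
  n <- length(a1); m <- length(a2)
  if (n == 0 && m == 0) return(0)
  M <- Ix <- Iy <- matrix(Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- a + b * i
  for (j in seq_len(m)) Iy[1, j + 1] <- a + b * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- min(M[i, j], Ix[i, j], Iy[i, j]) + d[a1[i], a2[j]]
    Ix[i + 1, j + 1] <- min(M[i, j + 1] + a + b, Ix[i, j + 1] + b,
                            Iy[i, j + 1] + a + b)
    Iy[i + 1, j + 1] <- min(M[i + 1, j] + a + b, Iy[i + 1, j] + b,
                            Ix[i + 1, j] + a + b)
  }
  min(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# brute-force star alignment: enumerate center sequences over a small
# alphabet up to a length cap
oracleCenter <- function(s1, s2, s3, model, affine, letters = c("A", "C"),
                         maxLen = NULL) {
  if (is.null(maxLen)) maxLen <- max(nchar(c(s1, s2, s3))) + 1
  pc <- function(x, y) if (affine) oracleGotoh(x, y, model) else
    oracleNW(x, y, model)
  cands <- ""
  for (l in seq_len(maxLen))
    cands <- c(cands, apply(expand.grid(rep(list(letters), l)), 1,
                            paste, collapse = ""))
  min(vapply(cands, function(m) pc(m, s1) + pc(m, s2) + pc(m, s3),
             numeric(1)))
}

# minimum pairwise cost over all contained-sequence pairs of two RAGs
bruteClosestPair <- function(A, B, model, affine, limit = 64) {
  ca <- containedSequences(A, limit)
  cb <- containedSequences(B, limit)
  pc <- if (affine) function(x, y) oracleGotoh(x, y, model) else
    function(x, y) oracleNW(x, y, model)
  min(outer(ca, cb, Vectorize(pc)))
}
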