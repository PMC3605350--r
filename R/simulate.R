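# simulate module: synthetic data emulating the benchmark design - random
# binary trees, root sequences evolved with substitutions and power-law
# indels, and uniform random triplets for the 3-leaf protocol.

#' Random binary tree with exponential branch lengths
#'
#' Uniform random binary topology (sequential random joins, via
#' \code{ape::rtree}) with i.i.d. exponential branch lengths of the given
#' mean.  \code{meanBranch = Inf} marks the saturation regime: every branch
#' is infinitely long and \code{\link{evolveSequences}} draws each child
#' sequence as a fresh uniform random sequence.
#'
#' @param nLeaves number of leaves (\eqn{\ge 2}).
#' @param meanBranch mean branch length (substitution time units), or
#'   \code{Inf}.
#' @param seed optional integer seed (set locally before drawing).
#' @return a rooted binary \code{phylo}
#' @export
randomTree <- function(nLeaves, meanBranch = 0.1, seed = NULL) {
  stopifnot(nLeaves >= 2L)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(nLeaves, rooted = TRUE)
  ne <- nrow(tr$edge)
  tr$edge.length <- if (is.infinite(meanBranch)) rep(Inf, ne) else
    rexp(ne, rate = 1 / meanBranch)
  tr
}

.powerLawLengths <- function(n, maxGap, exponent) {
  if (maxGap == 1L) return(rep(1L, n))
  sample.int(maxGap, n, replace = TRUE,
             prob = (seq_len(maxGap))^(-exponent))
}

.evolveBranch <- function(parent, t, substRate, indelRate, maxGap, exponent,
                          alphabet) {
  if (is.infinite(t))
    return(sample(alphabet, length(parent), replace = TRUE))
  s <- parent
  len <- length(s)
  if (len > 0L && substRate * t > 0) {
    # Jukes-Cantor-style: per-site change probability over time t
    p <- 0.75 * (1 - exp(-4 * substRate * t / 3))
    hit <- which(runif(len) < p)
    for (i in hit) s[i] <- sample(setdiff(alphabet, s[i]), 1L)
  }
  nev <- rpois(1L, indelRate * t * max(len, 1L))
  if (nev > 0L) {
    lens <- .powerLawLengths(nev, maxGap, exponent)
    for (k in seq_len(nev)) {
      klen <- lens[k]
      if (runif(1L) < 0.5 && length(s) >= klen) {        # deletion
        pos <- sample.int(length(s) - klen + 1L, 1L)
        s <- s[-(pos:(pos + klen - 1L))]
      } else {                                           # insertion
        pos <- sample.int(length(s) + 1L, 1L) - 1L       # insert after pos
        s <- append(s, sample(alphabet, klen, replace = TRUE), after = pos)
      }
    }
  }
  s
}

#' Evolve sequences down a tree
#'
#' Draws a uniform random root sequence and evolves it along every branch:
#' substitutions by a Jukes-Cantor-style per-site process at
#' \code{substRate} per unit branch length, and indel events at
#' \code{indelRate} per site per unit branch length, each an insertion or
#' deletion (equiprobable) with length drawn from a power law
#' \eqn{P(k) \propto k^{-powerExponent}} truncated at \code{maxGap}.
#' Returns both the leaf data and the true ancestral labeling, so heuristic
#' tree costs can be compared with the cost implied by the simulated
#' history.
#'
#' @param tree a rooted binary \code{phylo} with branch lengths (e.g. from
#'   \code{\link{randomTree}}).
#' @param rootLength root sequence length in bases.
#' @param substRate substitutions per site per unit branch length.
#' @param indelRate indel events per site per unit branch length.
#' @param maxGap maximum indel length (truncation).
#' @param powerExponent power-law exponent for indel lengths.
#' @param seed optional integer seed.
#' @param alphabet residue alphabet.
#' @return list with \code{leaf} (named character vector of leaf
#'   sequences), \code{labeling} (named character vector over all
#'   vertices) and \code{tree}
#' @export
evolveSequences <- function(tree, rootLength = 100L, substRate = 1.5,
                            indelRate = 0.05, maxGap = 5L,
                            powerExponent = 1.7, seed = NULL,
                            alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  if (rootLength < 1L || substRate < 0 || indelRate < 0 || maxGap < 1L)
    stop("invalid simulation parameters", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  nv <- ntip + tree$Nnode
  root <- .rootNode(tree)
  seqsv <- vector("list", nv)
  seqsv[[root]] <- sample(alphabet, rootLength, replace = TRUE)
  for (v in rev(.postorderNodes(tree))) {   # parents before children
    if (v == root) next
    e <- which(tree$edge[, 2L] == v)
    parent <- tree$edge[e, 1L]
    seqsv[[v]] <- .evolveBranch(seqsv[[parent]], tree$edge.length[e],
                                substRate, indelRate, maxGap, powerExponent,
                                alphabet)
  }
  lab <- vapply(seqsv, paste, character(1), collapse = "")
  names(lab) <- .vertexNames(tree)
  list(leaf = lab[seq_len(ntip)], labeling = lab, tree = tree)
}

#' Uniform random sequence triplets
#'
#' I.i.d. uniform DNA sequences grouped in triplets, for the 3-leaf exact
#' comparison protocol.
#'
#' @param nTriplets number of triplets.
#' @param lengths candidate sequence lengths; each sequence's length is
#'   drawn uniformly from this set.
#' @param seed optional integer seed.
#' @param alphabet residue alphabet.
#' @return list of character vectors of length 3
#' @export
randomTriplets <- function(nTriplets, lengths = 70:100, seed = NULL,
                           alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nTriplets), function(i)
    vapply(seq_len(3L), function(j) {
      len <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1)))
}
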