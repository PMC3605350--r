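# affine_align module: heuristic affine alignment of RAGs with the
# four-matrix recurrences, closest-pair extraction, and the indel-aware
# median m_affP.

#' Heuristic affine pairwise RAG alignment
#'
#' Fills four cost matrices over the powerset alphabet: \code{g} (both
#' columns align non-indel members), \code{d} (both select indels), \code{v}
#' (a column of A against an indel) and \code{h} (a column of B against an
#' indel), with accessory costs \code{subst}, \code{diag}, \code{go},
#' \code{go'} and \code{ge} handling where the gap opening \eqn{a} and
#' extension \eqn{b} apply; columns offering an indel can also be consumed
#' invisibly (their indel selected against nothing) at zero cost.  The
#' optimum is the minimum of the four matrices at the final cell and equals
#' the minimum Gotoh distance over all pairs of sequences contained in the
#' two RAGs, with block-grouped columns kept or dropped atomically (see
#' \linkS4class{Rag}).  On singleton RAGs this is exactly the Gotoh
#' alignment of the two plain sequences.
#'
#' Backtrack ties are broken deterministically: across matrices
#' \code{g > d > v > h}, within a matrix by case order (diagonal and
#' printed cases before invisible moves, take before skip).
#'
#' @param A,B \linkS4class{Rag} objects.
#' @param model a \linkS4class{CostModel}.
#' @param keepMatrices keep the four DP matrices in the result (for
#'   inspection; they are quadratic in the sequence lengths).
#' @return a \linkS4class{RagAlignment} with mode \code{"affine"}
#' @examples
#' m <- costModel(gapOpen = 7, gapExtend = 1)
#' a <- ragFromSequence("ATTA", m)
#' b <- ragFromSequence("ATA", m)
#' alignmentCost(affineDistanceRag(a, b, m))  # 8 = G(1) = 7 + 1
#' @export
affineDistanceRag <- function(A, B, model, keepMatrices = FALSE) {
  .requireTables(model)
  res <- cpp_align_rag_affine(A@masks, B@masks, A@groups, B@groups,
                              model@tables$dp,
                              length(model@alphabet) + 1L,
                              as.integer(round(model@gapOpen * model@scale)),
                              as.integer(round(model@gapExtend * model@scale)),
                              keepMatrices)
  im <- .indelMask(model)
  mats <- list()
  if (keepMatrices)
    mats <- lapply(res[c("g", "d", "v", "h")], function(m) m / model@scale)
  # aligned columns carry the *effective* masks (block decisions applied);
  # padding columns are {indel}
  ea <- as.integer(res$ea)
  eb <- as.integer(res$eb)
  consA <- ea != 0L
  consB <- eb != 0L
  ai <- integer(length(ea))
  bj <- integer(length(eb))
  ai[consA] <- seq_len(sum(consA))
  bj[consB] <- seq_len(sum(consB))
  ea[!consA] <- im
  eb[!consB] <- im
  new("RagAlignment", cost = res$cost / model@scale,
      alignedA = .newRag(ea, model),
      alignedB = .newRag(eb, model),
      trace = c("g", "d", "v", "h", "ia", "ib")[res$mats],
      ai = ai, bj = bj,
      mode = "affine", matrices = mats)
}

#' Accessory cost functions of the affine RAG recurrences
#'
#' Evaluates the accessory functions at aligned column positions
#' \code{i}, \code{j} of two RAGs: \code{subst(X,Y)}, the substitution cost
#' between the non-indel members (\code{Inf} when a side is pure indel);
#' \code{diag(X,Y)}, 0 when both sets contain the indel else \code{Inf};
#' \code{go(A,i)} / \code{go(B,j)}, the gap opening charge (0 when the
#' column starts an indel block: position 1 with an indel, or an indel
#' present with none in the previous column; else \eqn{a});
#' \code{goPrime(X,Y) = subst(X,Y) + a} if the indel is in \code{X} (else
#' \code{+ 0}); and \code{ge(X)}, the extension charge (0 when the indel is
#' in \code{X}, else \eqn{b}).
#'
#' @param A,B \linkS4class{Rag} objects.
#' @param i,j 1-based column positions in \code{A} and \code{B}.
#' @param model a \linkS4class{CostModel}.
#' @return list with \code{subst}, \code{diag}, \code{goA}, \code{goB},
#'   \code{goPrimeAB}, \code{goPrimeBA}, \code{geA}, \code{geB}
#' @export
accessoryCosts <- function(A, B, i, j, model) {
  ib <- .indelMask(model)
  hasIndel <- function(mask) bitwAnd(mask, ib) != 0L
  X <- A@masks[i]
  Y <- B@masks[j]
  sx <- bitwAnd(X, ib - 1L)
  sy <- bitwAnd(Y, ib - 1L)
  subst <- if (sx == 0L || sy == 0L) Inf else
    model@tables$dp[sx, sy] / model@scale
  go <- function(masks, k) {
    if (k == 1L && hasIndel(masks[k])) return(0)
    if (k > 1L && !hasIndel(masks[k - 1L]) && hasIndel(masks[k])) return(0)
    model@gapOpen
  }
  list(subst = subst,
       diag = if (hasIndel(X) && hasIndel(Y)) 0 else Inf,
       goA = go(A@masks, i), goB = go(B@masks, j),
       goPrimeAB = subst + if (hasIndel(X)) model@gapOpen else 0,
       goPrimeBA = subst + if (hasIndel(Y)) model@gapOpen else 0,
       geA = if (hasIndel(X)) 0 else model@gapExtend,
       geB = if (hasIndel(Y)) 0 else model@gapExtend)
}

# first non-indel member (alphabet order); mask must have one
.firstResidue <- function(mask, model) {
  .maskFirst(bitwAnd(mask, .indelMask(model) - 1L))
}

#' Extract a contained pair bounding the affine RAG distance
#'
#' Follows the optimal backtrack of \code{\link{affineDistanceRag}} and
#' selects members per column: on \code{g} steps the closest non-indel
#' member pair; on \code{h}/\code{v} steps an indel on the gapped side and,
#' on the other side, the indel when the set contains one (no cost to the
#' built alignment) or else its first member; on \code{d} steps indels on
#' both sides.  The resulting plain sequences \code{X}, \code{Y} are
#' contained in \code{A}, \code{B} and satisfy
#' \eqn{e_{aff}(X, Y) \le e_{affP}(A, B)} (with equality: the distance is
#' the exact closest-pair cost).
#'
#' @param res an affine \linkS4class{RagAlignment}.
#' @param model the \linkS4class{CostModel}.
#' @return \code{c(X, Y)}, two plain sequence strings
#' @export
extractClosestPairAffine <- function(res, model) {
  stopifnot(res@mode == "affine")
  sym <- c(model@alphabet, model@indel)
  ib <- .indelMask(model)
  noIndel <- ib - 1L
  am <- res@alignedA@masks
  bm <- res@alignedB@masks
  X <- Y <- character(length(res@trace))
  for (k in seq_along(res@trace)) {
    switch(res@trace[k],
      g = {
        sa <- bitwAnd(am[k], noIndel)
        sb <- bitwAnd(bm[k], noIndel)
        X[k] <- sym[model@tables$wx[sa, sb]]
        Y[k] <- sym[model@tables$wy[sa, sb]]
      },
      h = {
        X[k] <- model@indel
        Y[k] <- if (bitwAnd(bm[k], ib) != 0L) model@indel else
          sym[.maskFirst(bm[k])]
      },
      v = {
        Y[k] <- model@indel
        X[k] <- if (bitwAnd(am[k], ib) != 0L) model@indel else
          sym[.maskFirst(am[k])]
      },
      d = {
        X[k] <- model@indel
        Y[k] <- model@indel
      },
      ia = {          # invisible: A_i selects its indel, B not consumed
        X[k] <- model@indel
        Y[k] <- model@indel
      },
      ib = {
        X[k] <- model@indel
        Y[k] <- model@indel
      })
  }
  c(paste(X[X != model@indel], collapse = ""),
    paste(Y[Y != model@indel], collapse = ""))
}

#' Affine median RAG m_affP
#'
#' Builds the RAG stored at an internal vertex by Affine-DO.  Along the
#' optimal backtrack, match (\code{g}) columns contribute the non-indel
#' members of \eqn{A_i} and \eqn{B_j} mutually realizing the substitution
#' distance; columns where indels were selected on both sides (\code{d} and
#' invisible steps) contribute nothing.  Gap steps (\code{h} consuming
#' \eqn{B_j}, \code{v} consuming \eqn{A_i}) with no indel available in the
#' consumed set are the visible residues of a gap block.  A block consisting
#' of a single such column is stored with its indel option,
#' \eqn{\{indel\} \cup B_j}, so downstream selections may keep or drop the
#' residue; blocks with two or more visible columns are stored without the
#' indel option (kept whole).  This all-or-nothing treatment prevents later
#' selections from splitting a gap block - a split would introduce gap
#' openings the traversal never charged, losing the upper-bound guarantee
#' (the known failure mode of the non-affine median under affine costs).
#' Pure-indel columns are removed at the end.
#'
#' @param res an affine \linkS4class{RagAlignment}.
#' @param model the \linkS4class{CostModel}.
#' @return a \linkS4class{Rag}
#' @export
medianAffine <- function(res, model) {
  stopifnot(res@mode == "affine")
  ib <- .indelMask(model)
  am <- res@alignedA@masks
  bm <- res@alignedB@masks
  tr <- res@trace
  n <- length(tr)
  masks <- integer(0)
  groups <- integer(0)
  nextGroup <- 0L
  emitBlock <- function(vis) {        # vis: visible gap-column masks
    if (!length(vis)) return(invisible(NULL))
    if (length(vis) == 1L) {
      masks <<- c(masks, bitwOr(vis, ib))
      groups <<- c(groups, 0L)
    } else {
      nextGroup <<- nextGroup + 1L
      masks <<- c(masks, bitwOr(vis, ib))
      groups <<- c(groups, rep(nextGroup, length(vis)))
    }
    invisible(NULL)
  }
  flushSegment <- function(from, to) {
    if (to < from) return(invisible(NULL))
    idx <- from:to
    # A-side residues first, then B-side; the relative order of the two
    # sides' insertions within one gap segment is a convention
    emitBlock(am[idx[tr[idx] == "v" & bitwAnd(am[idx], ib) == 0L]])
    emitBlock(bm[idx[tr[idx] == "h" & bitwAnd(bm[idx], ib) == 0L]])
    invisible(NULL)
  }
  segStart <- 1L
  for (k in seq_len(n)) {
    if (tr[k] == "g") {
      flushSegment(segStart, k - 1L)
      masks <- c(masks, model@tables$medaff[am[k], bm[k]])
      groups <- c(groups, 0L)
      segStart <- k + 1L
    }
  }
  flushSegment(segStart, n)
  keep <- masks != 0L & masks != ib
  .newRag(masks[keep], model, groups[keep])
}

#' Plain-sequence affine alignment cost (Gotoh)
#'
#' Exact optimal pairwise alignment cost under gap cost
#' \eqn{G(k) = a + bk}, computed with the classic three-matrix Gotoh
#' dynamic program (match / gap-in-A / gap-in-B states).  This is an
#' implementation independent of the four-matrix RAG recurrences and is
#' used to price tree edges of a vertex labeling in affine mode.
#'
#' @param s1,s2 character strings over the residue alphabet.
#' @param model a \linkS4class{CostModel}.
#' @return the optimal cost
#' @examples
#' m <- costModel(gapOpen = 7, gapExtend = 1)
#' gotohCost("ATTA", "ATTTA", m)  # 8
#' @export
gotohCost <- function(s1, s2, model) {
  cpp_gotoh(.encodeSeq(s1, model), .encodeSeq(s2, model), model@icosts,
            as.integer(round(model@gapOpen * model@scale)),
            as.integer(round(model@gapExtend * model@scale))) / model@scale
}

# edge pricing dispatch shared by the tree modules
.pairCost <- function(s1, s2, model, mode) {
  if (mode == "affine") gotohCost(s1, s2, model) else editCost(s1, s2, model)
}
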