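# nonaffine_align module: pairwise RAG alignment under G(k) = bk,
# closest-pair extraction, and the median m_P.

.requireTables <- function(model) {
  if (!.hasTables(model))
    stop("alignment requires the precomputed powerset tables; the model's ",
         "alphabet exceeds the table cap (see ?costModel)", call. = FALSE)
}

.alignedMasks <- function(masks, idx, indelMask) {
  out <- rep(indelMask, length(idx))
  out[idx > 0L] <- masks[idx[idx > 0L]]
  as.integer(out)
}

#' Pairwise RAG edit distance under the non-affine model
#'
#' Needleman-Wunsch dynamic programming over the powerset alphabet, with
#' substitution cost \eqn{d_P(A_i, B_j)} and indel cost
#' \eqn{d_P(\cdot, \{indel\})}.  The optimal cost equals the minimum plain
#' edit distance over all pairs of sequences contained in the two RAGs.
#' Backtrack ties are broken deterministically: diagonal, then delete
#' (consume A), then insert (consume B).
#'
#' @param A,B \linkS4class{Rag} objects (possibly empty).
#' @param model a \linkS4class{CostModel}.
#' @return a \linkS4class{RagAlignment}
#' @examples
#' m <- costModel()
#' a <- ragFromSequence("ATTG", m)
#' b <- ragFromSequence("ATC", m)
#' editDistanceRag(a, b, m)
#' @export
editDistanceRag <- function(A, B, model) {
  .requireTables(model)
  res <- cpp_align_rag(A@masks, B@masks, model@tables$dp, .indelMask(model))
  im <- .indelMask(model)
  new("RagAlignment", cost = res$cost / model@scale,
      alignedA = .newRag(.alignedMasks(A@masks, res$ai, im), model),
      alignedB = .newRag(.alignedMasks(B@masks, res$bj, im), model),
      trace = c("diagonal", "delete", "insert")[res$ops],
      ai = as.integer(res$ai), bj = as.integer(res$bj),
      mode = "nonaffine", matrices = list())
}

# member of a set closest to indel: indel itself when present, else the
# alphabetically first member (d(x, indel) = b uniformly)
.closestToIndel <- function(mask, model) {
  ib <- .indelMask(model)
  if (bitwAnd(mask, ib) != 0L) length(model@alphabet) + 1L else .maskFirst(mask)
}

#' Extract a closest contained pair from a pairwise RAG alignment
#'
#' Walks the optimal backtrack and selects one member per column: on
#' diagonal steps the witness pair realizing \eqn{d_P}, on indel steps the
#' member closest to indel (the indel itself when present, else the
#' alphabet-first member).  The returned plain sequences \code{U}, \code{V}
#' are contained in \code{A} and \code{B} and satisfy
#' \eqn{e(U, V) = e_P(A, B)}.
#'
#' @param res a non-affine \linkS4class{RagAlignment}.
#' @param model the \linkS4class{CostModel} used to build it.
#' @return \code{c(U, V)}, two plain sequence strings
#' @export
extractClosestPair <- function(res, model) {
  stopifnot(res@mode == "nonaffine")
  sym <- c(model@alphabet, model@indel)
  nsym <- length(sym)
  am <- res@alignedA@masks
  bm <- res@alignedB@masks
  U <- V <- character(length(res@trace))
  for (k in seq_along(res@trace)) {
    switch(res@trace[k],
      diagonal = {
        U[k] <- sym[model@tables$wx[am[k], bm[k]]]
        V[k] <- sym[model@tables$wy[am[k], bm[k]]]
      },
      delete = {
        U[k] <- sym[.closestToIndel(am[k], model)]
        V[k] <- model@indel
      },
      insert = {
        U[k] <- model@indel
        V[k] <- sym[.closestToIndel(bm[k], model)]
      })
  }
  c(paste(U[U != model@indel], collapse = ""),
    paste(V[V != model@indel], collapse = ""))
}

#' Median RAG of an aligned pair (non-affine)
#'
#' Column \eqn{i} of the median is \eqn{m(A_i, B_i)}: the set of members of
#' the two aligned columns that participate in a pair realizing
#' \eqn{d_P(A_i, B_i)}.  The median has the aligned length; pure-indel
#' columns are retained (they vanish on sequence selection).  Every sequence
#' contained in the median lies on an optimal edit path between the inputs.
#'
#' @param res a non-affine \linkS4class{RagAlignment}.
#' @param model the \linkS4class{CostModel}.
#' @return a \linkS4class{Rag}
#' @export
medianNonaffine <- function(res, model) {
  stopifnot(res@mode == "nonaffine")
  if (!length(res@trace)) return(.newRag(integer(0), model))
  masks <- model@tables$med[cbind(res@alignedA@masks, res@alignedB@masks)]
  .newRag(masks, model)
}

#' Plain-sequence edit distance (Needleman-Wunsch)
#'
#' Optimal pairwise alignment cost of two plain sequences under the model's
#' substitution matrix with per-indel cost \eqn{b} (no gap opening).  Used
#' to price tree edges of a vertex labeling in non-affine mode.
#'
#' @param s1,s2 character strings over the residue alphabet.
#' @param model a \linkS4class{CostModel}.
#' @return the optimal cost
#' @export
editCost <- function(s1, s2, model) {
  cpp_nw(.encodeSeq(s1, model), .encodeSeq(s2, model), model@icosts,
         length(model@alphabet) + 1L) / model@scale
}

#' @rdname RagAlignment-class
#' @param x a \code{RagAlignment}
#' @export
setMethod("alignmentCost", "RagAlignment", function(x) x@cost)

#' @rdname RagAlignment-class
#' @export
setMethod("alignedRags", "RagAlignment",
          function(x) list(A = x@alignedA, B = x@alignedB))

#' @rdname RagAlignment-class
#' @export
setMethod("alignmentTrace", "RagAlignment", function(x) x@trace)

setMethod("show", "RagAlignment", function(object) {
  cat("RagAlignment (", object@mode, "), cost ", object@cost, "\n",
      "  A: ", ragToString(object@alignedA), "\n",
      "  B: ", ragToString(object@alignedB), "\n", sep = "")
})
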