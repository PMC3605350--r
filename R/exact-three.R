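# exact_small module: exact star alignment of three sequences (the
# optimality yardstick for 3-leaf trees), non-affine and affine.

#' Exact three-sequence (star) alignment
#'
#' Computes a center sequence \eqn{m} minimizing
#' \eqn{\sum_i e(m, s_i)} over all possible center sequences, where each
#' center-to-leaf term is an independent optimal pairwise alignment cost.
#' This is the exact optimum of the tree alignment problem on an unrooted
#' 3-leaf star.  Non-affine mode uses the classic three-dimensional dynamic
#' program (each column advances a subset of the sequences against a center
#' residue or a center gap); affine mode augments every cell with a
#' per-edge gap-open state (residue-aligned / gap in the sequence / gap in
#' the center), keeping two DP planes in memory for the cost.
#'
#' The cubic DP is intended for short sequences; calls beyond
#' \code{maxLength} are refused.
#'
#' @param s1,s2,s3 character strings over the residue alphabet.
#' @param model a \linkS4class{CostModel}.
#' @param mode \code{"auto"} picks affine when the model's gap opening cost
#'   is positive.
#' @param median also reconstruct an optimal center sequence (stores a full
#'   backtrack; memory grows as the product of the three lengths).
#' @param maxLength refuse sequences longer than this.
#' @return list with \code{cost} and (when requested) \code{median}
#' @examples
#' m <- costModel(subst = 2, gapOpen = 1, gapExtend = 1)
#' exactThreeAlignment("ACGT", "AGT", "ACT", m)
#' @export
exactThreeAlignment <- function(s1, s2, s3, model,
                                mode = c("auto", "nonaffine", "affine"),
                                median = TRUE, maxLength = 120L) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (model@gapOpen > 0) "affine" else "nonaffine"
  lens <- c(nchar(s1), nchar(s2), nchar(s3))
  if (any(lens > maxLength))
    stop("sequence length ", max(lens), " exceeds the exact-alignment cap (",
         maxLength, "); the three-dimensional DP is cubic - use the DO ",
         "heuristics for longer sequences", call. = FALSE)
  e1 <- .encodeSeq(s1, model) - 1L   # 0-based residue codes
  e2 <- .encodeSeq(s2, model) - 1L
  e3 <- .encodeSeq(s3, model) - 1L
  nres <- length(model@alphabet)
  if (mode == "nonaffine") {
    res <- cpp_exact3(e1, e2, e3, model@icosts, nres, nres + 1L, median)
  } else {
    res <- cpp_exact3_affine(e1, e2, e3, model@icosts, nres,
                             as.integer(round(model@gapOpen * model@scale)),
                             as.integer(round(model@gapExtend * model@scale)),
                             median)
  }
  out <- list(cost = res$cost / model@scale, mode = mode)
  if (median)
    out$median <- paste(model@alphabet[res$median], collapse = "")
  out
}
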