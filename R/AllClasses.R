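#' @importFrom methods new setClass setGeneric setMethod setValidity validObject is
#' @importFrom stats rexp rpois runif
#' @importFrom utils head tail
NULL

setOldClass("phylo")

#' Edit cost model over a residue alphabet extended with an indel symbol
#'
#' A \code{CostModel} holds the ordered residue alphabet \eqn{\Sigma}, the
#' distinguished indel symbol, a symmetric substitution cost matrix
#' \eqn{d(x,y)} over \eqn{\Sigma \cup \{indel\}}, and the affine gap
#' parameters: gap opening cost \eqn{a} and gap extension cost \eqn{b}, so a
#' run of \eqn{k} indels costs \eqn{G(k) = a + bk}.  The model requires
#' \eqn{d(x, indel) = b} for every residue \eqn{x}, \eqn{d(x,x)=0}, symmetry,
#' and non-negative finite costs.
#'
#' All dynamic programming runs on exact scaled integers: input costs
#' (possibly decimal, e.g. quarter-unit schemes) are multiplied by a common
#' denominator detected at construction, and results are rescaled on output,
#' so backtrack tie comparisons are never subject to floating point noise.
#' For alphabets of at most \code{maxTableSymbols} symbols (indel included)
#' the full powerset distance, witness and median tables are precomputed for
#' constant-time lookups during alignment.
#'
#' @slot alphabet character vector of residues, in the fixed order used for
#'   bitset encoding and tie breaking.
#' @slot indel the indel symbol (always ordered last).
#' @slot costs numeric substitution cost matrix over
#'   \code{c(alphabet, indel)}, original scale.
#' @slot gapOpen,gapExtend the affine parameters \eqn{a} and \eqn{b}.
#' @slot scale integer denominator: internal cost = \code{round(cost * scale)}.
#' @slot icosts integer scaled cost matrix.
#' @slot tables list of powerset lookup tables (\code{dp}, \code{wx},
#'   \code{wy}, \code{med}, \code{medaff}), or empty when the alphabet
#'   exceeds the table cap.
#' @export
setClass("CostModel",
  representation(alphabet = "character", indel = "character",
                 costs = "matrix", gapOpen = "numeric", gapExtend = "numeric",
                 scale = "integer", icosts = "matrix", tables = "list"))

#' Reduced Alignment Graph: a sequence over the powerset alphabet
#'
#' A \code{Rag} is a sequence whose positions are nonempty subsets of
#' \eqn{\Sigma \cup \{indel\}} (the powerset alphabet
#' \eqn{\Sigma_P = P(\Sigma) \setminus \{\emptyset\}}).  It compactly encodes
#' the set of plain sequences obtained by selecting one member per column and
#' deleting the indels.  Columns are stored as integer bitmasks keyed to the
#' model's symbol order (indel = highest bit).
#'
#' In the affine model, a median may store an optional gap block - the
#' visible residues of an insertion/deletion run - as a group of columns
#' marked with a shared nonzero id in \code{groups}.  Sequence selections
#' treat such a block atomically: either every column of the group
#' contributes a residue, or every column contributes an indel.  This keeps
#' a later selection from splitting a gap block, which would introduce gap
#' openings never priced by the traversal.  Ordinary columns carry group
#' id 0.
#'
#' @slot masks integer vector of column bitmasks (each in
#'   \code{1 .. 2^nsym - 1}).
#' @slot symbols the full symbol order \code{c(alphabet, indel)} the masks
#'   are keyed to.
#' @slot groups integer vector of block-group ids (0 = ordinary column;
#'   equal consecutive nonzero ids form one atomic optional block).
#' @export
setClass("Rag", representation(masks = "integer", symbols = "character",
                               groups = "integer"))

setValidity("Rag", function(object) {
  nset <- bitwShiftL(1L, length(object@symbols)) - 1L
  if (length(object@masks) &&
      (any(object@masks < 1L) || any(object@masks > nset)))
    return("every RAG column must be a nonempty subset of the symbol set")
  if (length(object@groups) != length(object@masks))
    return("groups must have one entry per column")
  g <- object@groups
  if (length(g) && any(g != 0L)) {
    nz <- which(g != 0L)
    for (id in unique(g[nz])) {
      w <- which(g == id)
      if (any(diff(w) != 1L))
        return("block-group columns must be consecutive")
    }
    ib <- bitwShiftL(1L, length(object@symbols) - 1L)
    if (any(bitwAnd(object@masks[nz], ib) == 0L))
      return("block-group columns must carry the indel option")
  }
  TRUE
})

#' Result of a pairwise RAG alignment
#'
#' Holds the optimal cost, the pair of equal-length indel-padded aligned
#' RAGs, and one optimal backtrack.  For the non-affine model the trace steps
#' are \code{"diagonal"}, \code{"delete"} (consumes a column of A) and
#' \code{"insert"} (consumes a column of B), and the aligned RAGs carry the
#' input columns.  For the affine model the steps name the DP matrix each
#' column was taken from (\code{"g"}, \code{"d"}, \code{"v"}, \code{"h"}) or
#' an invisible single-column consumption (\code{"ia"}, \code{"ib"}), and
#' the aligned RAGs carry the \emph{effective} column sets, with any
#' block-group decisions (take or skip) already applied.
#'
#' @slot cost optimal alignment cost (original cost scale).
#' @slot alignedA,alignedB the aligned RAGs, padded with \{indel\} columns.
#' @slot trace character vector of per-column step tags.
#' @slot ai,bj 1-based input column consumed at each alignment column
#'   (0 where the side is padding).
#' @slot mode \code{"nonaffine"} or \code{"affine"}.
#' @slot matrices for affine alignments built with
#'   \code{keepMatrices = TRUE}, the four cost matrices \code{g}, \code{d},
#'   \code{v}, \code{h} (original scale, \code{Inf} for the sentinel);
#'   otherwise an empty list.
#' @export
setClass("RagAlignment",
  representation(cost = "numeric", alignedA = "Rag", alignedB = "Rag",
                 trace = "character", ai = "integer", bj = "integer",
                 mode = "character", matrices = "list"))

#' Result of a DO / Affine-DO post-order traversal
#'
#' @slot tree the rooted binary \code{phylo} tree.
#' @slot rags list of per-vertex RAGs \eqn{S(v)}, indexed by vertex number.
#' @slot cost the accumulated traversal cost: a feasible upper bound on the
#'   tree alignment cost.
#' @slot mode \code{"nonaffine"} (DO) or \code{"affine"} (Affine-DO).
#' @slot model the \code{CostModel} used.
#' @export
setClass("DoTraversal",
  representation(tree = "phylo", rags = "list", cost = "numeric",
                 mode = "character", model = "CostModel"))
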