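# tree_engine module: DO and Affine-DO post-order traversals, pre-order
# backtrack assignment, labeling evaluation, and rooting.

.alignRag <- function(A, B, model, mode) {
  if (mode == "affine") affineDistanceRag(A, B, model)
  else editDistanceRag(A, B, model)
}

.medianRag <- function(aln, model) {
  if (aln@mode == "affine") medianAffine(aln, model)
  else medianNonaffine(aln, model)
}

.doTraverse <- function(tree, seqs, model, mode) {
  .checkBinaryRooted(tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(seqs))
  if (length(missing))
    stop("no sequence for leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ntip <- length(tips)
  ch <- .childrenList(tree)
  rags <- vector("list", ntip + tree$Nnode)
  cost <- 0
  for (v in .postorderNodes(tree)) {
    if (v <= ntip) {
      rags[[v]] <- ragFromSequence(seqs[[tips[v]]], model)
    } else {
      u <- ch[[v]][1L]
      w <- ch[[v]][2L]
      aln <- .alignRag(rags[[u]], rags[[w]], model, mode)
      cost <- cost + aln@cost
      rags[[v]] <- .medianRag(aln, model)
    }
  }
  new("DoTraversal", tree = tree, rags = rags, cost = cost, mode = mode,
      model = model)
}

#' Direct Optimization traversal (non-affine)
#'
#' Post-order traversal of a rooted binary tree: each leaf gets the
#' singleton-column RAG of its sequence; each internal vertex accumulates
#' the pairwise RAG edit distance \eqn{e_P} of its two children and stores
#' the median RAG \eqn{m_P} of their aligned columns.  The accumulated cost
#' is a feasible upper bound on the tree alignment cost: a compatible
#' vertex labeling realizing it exactly is recovered by
#' \code{\link{backtrackAssignment}}.
#'
#' @param tree a rooted binary \code{phylo} tree whose tip labels name
#'   \code{seqs}.
#' @param seqs named character vector (or list) of leaf sequences.
#' @param model a \linkS4class{CostModel}; the gap opening cost is ignored
#'   in non-affine mode.
#' @return a \linkS4class{DoTraversal}
#' @examples
#' m <- costModel()
#' tr <- ape::read.tree(text = "((a,b),c);")
#' fit <- doTraversal(tr, c(a = "ACGT", b = "ACT", c = "AGT"), m)
#' traversalCost(fit)
#' @export
doTraversal <- function(tree, seqs, model) {
  .doTraverse(tree, seqs, model, "nonaffine")
}

#' Affine-DO traversal
#'
#' As \code{\link{doTraversal}} but with the affine pairwise RAG distance
#' \eqn{e_{affP}} and the indel-aware median \eqn{m_{affP}}.  The cost is an
#' upper bound on the affine tree alignment cost;
#' \code{\link{backtrackAssignment}} recovers a labeling of cost at most
#' the bound.
#'
#' With a zero gap opening cost the affine gap function \eqn{G(k) = bk} is
#' the non-affine model, so the traversal reduces to plain DO (identical
#' costs and medians).
#'
#' @inheritParams doTraversal
#' @return a \linkS4class{DoTraversal}
#' @export
affineDoTraversal <- function(tree, seqs, model) {
  if (model@gapOpen == 0) return(.doTraverse(tree, seqs, model, "nonaffine"))
  .doTraverse(tree, seqs, model, "affine")
}

# deterministic contained-sequence selection at the root: per column the
# alphabetically first non-indel member, else the indel (then stripped)
.rootSequence <- function(rag, model) {
  noIndel <- .indelMask(model) - 1L
  sym <- model@alphabet
  res <- bitwAnd(rag@masks, noIndel)
  paste(vapply(res[res != 0L], function(m) sym[.maskFirst(m)], character(1)),
        collapse = "")
}

#' Recover a compatible vertex labeling from a traversal
#'
#' Pre-order backtrack: the root is labeled with a deterministic sequence
#' contained in \eqn{S(\rho)}; every other internal vertex is labeled with
#' the sequence contained in its \eqn{S(v)} closest to its parent's label,
#' found by aligning the parent label (as a singleton RAG) against
#' \eqn{S(v)} and extracting the closest pair.  Leaves keep their input
#' sequences, so the labeling is compatible with the leaf data.  In
#' non-affine mode the labeling's edge-sum cost equals the traversal cost
#' exactly; in affine mode it is at most the traversal cost.
#'
#' @param fit a \linkS4class{DoTraversal}.
#' @return a named character vector of per-vertex sequences (names from the
#'   tip labels and internal vertex names)
#' @export
backtrackAssignment <- function(fit) {
  tree <- fit@tree
  model <- fit@model
  ntip <- length(tree$tip.label)
  nv <- ntip + tree$Nnode
  ch <- .childrenList(tree)
  lab <- character(nv)
  root <- .rootNode(tree)
  lab[root] <- .rootSequence(fit@rags[[root]], model)
  for (v in rev(.postorderNodes(tree))) {   # parents before children
    if (v == root) next
    parent <- tree$edge[tree$edge[, 2L] == v, 1L]
    if (v <= ntip) {
      lab[v] <- .rootSequence(fit@rags[[v]], model)  # the leaf sequence
    } else {
      aln <- .alignRag(ragFromSequence(lab[parent], model), fit@rags[[v]],
                       model, fit@mode)
      pair <- if (fit@mode == "affine")
        extractClosestPairAffine(aln, model) else
        extractClosestPair(aln, model)
      lab[v] <- pair[2L]
    }
  }
  names(lab) <- .vertexNames(tree)
  lab
}

#' Edge-sum cost of a vertex labeling
#'
#' The ground-truth tree cost of a full labeling: the sum over tree edges of
#' the optimal pairwise alignment cost of the endpoint sequences
#' (Needleman-Wunsch in non-affine mode, Gotoh in affine mode).
#'
#' @param tree a rooted binary \code{phylo} tree.
#' @param labeling named character vector covering every vertex (names as in
#'   \code{\link{backtrackAssignment}}).
#' @param model a \linkS4class{CostModel}.
#' @param mode \code{"nonaffine"} or \code{"affine"} edge pricing.
#' @return the total cost
#' @export
evaluateLabeling <- function(tree, labeling, model,
                             mode = c("nonaffine", "affine")) {
  mode <- match.arg(mode)
  vn <- .vertexNames(tree)
  missing <- setdiff(vn, names(labeling))
  if (length(missing))
    stop("labeling is missing vertex/vertices: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lab <- labeling[vn]
  total <- 0
  for (e in seq_len(nrow(tree$edge)))
    total <- total + .pairCost(lab[[tree$edge[e, 1L]]],
                               lab[[tree$edge[e, 2L]]], model, mode)
  total
}

#' Root an unrooted binary tree on an edge
#'
#' Places a degree-two root by subdividing the chosen edge (default: the
#' first edge in the tree's edge matrix).  An already binary-rooted tree is
#' returned unchanged.  Non-affine DO costs do not depend on the rooting
#' edge choice in theory for symmetric costs; affine costs may, so the CLI
#' reports the root used.
#'
#' @param tree a \code{phylo} tree, rooted-binary or with a basal
#'   trifurcation (ape's unrooted representation).
#' @param edge row index into \code{tree$edge} of the edge to root on.
#' @return a rooted binary \code{phylo}
#' @export
rootTree <- function(tree, edge = 1L) {
  ch <- .childrenList(tree)
  ndeg <- lengths(ch[(length(tree$tip.label) + 1L):length(ch)])
  if (all(ndeg == 2L)) return(tree)          # already rooted binary
  root <- .rootNode(tree)
  if (!(length(ch[[root]]) == 3L && all(ndeg[-1L] == 2L)))
    stop("tree is not binary", call. = FALSE)
  v <- tree$edge[edge, 2L]
  out <- ape::root(tree, outgroup = .tipsBelow(tree, v),
                   resolve.root = TRUE)
  .checkBinaryRooted(out)
  out
}

#' @rdname DoTraversal-class
#' @param x a \code{DoTraversal}
#' @export
setMethod("traversalCost", "DoTraversal", function(x) x@cost)

#' @rdname DoTraversal-class
#' @export
setMethod("vertexRags", "DoTraversal", function(x) {
  names(x@rags) <- .vertexNames(x@tree)
  x@rags
})

setMethod("show", "DoTraversal", function(object) {
  cat("DoTraversal (", if (object@mode == "affine") "Affine-DO" else "DO",
      ") over ", length(object@tree$tip.label), " leaves; cost ",
      object@cost, "\n", sep = "")
})
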