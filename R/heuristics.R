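# heuristics module: Fixed States initial assignment and iterative
# improvement (approximate via DO/Affine-DO rooted triples, exact via the
# three-dimensional alignment).

.distanceMode <- function(model, distance) {
  if (distance != "auto") return(distance)
  if (model@gapOpen > 0) "affine" else "nonaffine"
}

#' Fixed States assignment
#'
#' Restricts internal vertex labels to the input leaf sequences and finds
#' the optimal such labeling by dynamic programming over the tree (state
#' space = leaf sequences, edge weights = pairwise alignment costs).  This
#' is the Fixed States algorithm, a 2-approximation to the tree alignment
#' optimum.
#'
#' @param tree a rooted binary \code{phylo} tree.
#' @param seqs named character vector of leaf sequences.
#' @param model a \linkS4class{CostModel}.
#' @param distance edge pricing: \code{"auto"} picks affine when the
#'   model's gap opening cost is positive.
#' @return list with \code{labeling} (named character vector) and
#'   \code{cost} (its \code{\link{evaluateLabeling}} edge-sum)
#' @export
fixedStates <- function(tree, seqs, model,
                        distance = c("auto", "nonaffine", "affine")) {
  distance <- .distanceMode(model, match.arg(distance))
  .checkBinaryRooted(tree)
  tips <- tree$tip.label
  if (length(tips) < 2L) stop("need at least two leaves")
  states <- vapply(tips, function(t) seqs[[t]], character(1))
  ns <- length(states)
  D <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns)
    D[i, j] <- D[j, i] <- .pairCost(states[i], states[j], model, distance)

  ntip <- length(tips)
  nv <- ntip + tree$Nnode
  ch <- .childrenList(tree)
  INF <- Inf
  M <- matrix(INF, nv, ns)
  for (v in .postorderNodes(tree)) {
    if (v <= ntip) {
      M[v, v] <- 0
    } else {
      acc <- rep(0, ns)
      for (u in ch[[v]]) {
        # best child state per own state s: min_t M[u,t] + D[s,t]
        acc <- acc + apply(D + rep(M[u, ], each = ns), 1L, min)
      }
      M[v, ] <- acc
    }
  }
  root <- .rootNode(tree)
  pick <- integer(nv)
  pick[root] <- which.min(M[root, ])
  for (v in rev(.postorderNodes(tree))) {
    if (v <= ntip) next
    s <- pick[v]
    for (u in ch[[v]]) pick[u] <- which.min(M[u, ] + D[s, ])
  }
  lab <- states[pick]
  lab[seq_len(ntip)] <- states            # leaves keep their own sequences
  names(lab) <- .vertexNames(tree)
  list(labeling = lab,
       cost = evaluateLabeling(tree, lab, model, distance))
}

# unrooted-view neighbors of internal non-root vertex v: its children plus
# its parent, with the root (degree 2) seen through to its other child
.unrootedNeighbors <- function(tree, v, ch) {
  root <- .rootNode(tree)
  parent <- tree$edge[tree$edge[, 2L] == v, 1L]
  up <- if (parent == root) setdiff(ch[[root]], v) else parent
  c(ch[[v]], up)
}

#' Iterative improvement of a vertex labeling
#'
#' Sweeps the internal vertices (unrooted view: the two children of the
#' root are mutual neighbors) in post-order.  For each vertex it proposes
#' replacement medians of its three neighbors' current labels - in
#' \code{"approx"} mode the DO/Affine-DO assignments of the three possible
#' rooted triples, in \code{"exact"} mode the exact three-dimensional
#' alignment center - and replaces the label when the summed cost of the
#' three adjacent edges strictly decreases (ties keep the incumbent).
#' Stops after a sweep with no change or after \code{maxIter} sweeps.  The
#' total labeling cost is non-increasing sweep by sweep.
#'
#' @param tree a rooted binary \code{phylo} tree.
#' @param labeling a complete named labeling, e.g. from
#'   \code{\link{backtrackAssignment}} or \code{\link{fixedStates}}.
#' @param model a \linkS4class{CostModel}.
#' @param mode median proposal scheme, \code{"approx"} or \code{"exact"}.
#' @param maxIter maximum number of sweeps.
#' @param distance edge pricing, as in \code{\link{fixedStates}}.
#' @return list with \code{labeling}, \code{cost}, and \code{sweeps} run
#' @export
iterativeImprove <- function(tree, labeling, model,
                             mode = c("approx", "exact"), maxIter = 10L,
                             distance = c("auto", "nonaffine", "affine")) {
  mode <- match.arg(mode)
  distance <- .distanceMode(model, match.arg(distance))
  .checkBinaryRooted(tree)
  stopifnot(maxIter >= 1L)
  vn <- .vertexNames(tree)
  lab <- labeling[vn]
  names(lab) <- vn
  ntip <- length(tree$tip.label)
  root <- .rootNode(tree)
  ch <- .childrenList(tree)
  inner <- setdiff(.postorderNodes(tree)[.postorderNodes(tree) > ntip], root)

  tripleMedians <- function(n1, n2, n3) {
    if (mode == "exact")
      return(exactThreeAlignment(n1, n2, n3, model, mode = distance)$median)
    combs <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
    seqsv <- c(n1, n2, n3)
    vapply(combs, function(cb) {
      tr <- ape::read.tree(text = "((l1,l2),l3);")
      sq <- c(l1 = seqsv[cb[1L]], l2 = seqsv[cb[2L]], l3 = seqsv[cb[3L]])
      fit <- .doTraverse(tr, sq, model, distance)
      backtrackAssignment(fit)[["v5"]]     # the cherry vertex
    }, character(1))
  }

  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (v in inner) {
      nb <- .unrootedNeighbors(tree, v, ch)
      nbl <- lab[nb]
      inc <- sum(vapply(nbl, .pairCost, numeric(1), s1 = lab[[v]],
                        model = model, mode = distance))
      for (cand in unique(tripleMedians(nbl[[1L]], nbl[[2L]], nbl[[3L]]))) {
        cc <- sum(vapply(nbl, .pairCost, numeric(1), s1 = cand,
                         model = model, mode = distance))
        if (cc < inc) {
          lab[v] <- cand
          inc <- cc
          changed <- TRUE
        }
      }
    }
    # re-derive the degree-2 root: incumbent vs either child label,
    # whichever minimizes the two root edges (ties keep the earlier option)
    u <- ch[[root]][1L]
    w <- ch[[root]][2L]
    rcand <- c(lab[[root]], lab[[u]], lab[[w]])
    rcost <- vapply(rcand, function(x)
      .pairCost(x, lab[[u]], model, distance) +
      .pairCost(x, lab[[w]], model, distance), numeric(1))
    lab[root] <- rcand[[which.min(rcost)]]
    if (!changed || sweeps >= maxIter) break
  }
  list(labeling = lab,
       cost = evaluateLabeling(tree, lab, model, distance),
       sweeps = sweeps)
}
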