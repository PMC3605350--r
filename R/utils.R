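# Internal helpers shared across modules. Residue sets are bitmasks over the
# symbol order (alphabet first, indel last); masks run 1 .. 2^nsym - 1.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.splitSeq <- function(x) {
  if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1L]]
}

# symbol characters -> 1-based index in the full symbol order (incl. indel)
.symbolIndex <- function(chars, symbols, what = "sequence") {
  idx <- match(chars, symbols)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("unknown symbol(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

# plain sequence string -> 1-based residue indices (indel not allowed)
.encodeSeq <- function(s, model) {
  chars <- .splitSeq(s)
  sym <- alphabet(model)
  idx <- match(chars, sym)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("sequence contains symbols outside the residue alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

.decodeSeq <- function(idx, model) {
  paste(alphabet(model)[idx], collapse = "")
}

.maskFromIndices <- function(idx) as.integer(sum(bitwShiftL(1L, idx - 1L)))

.maskMembers <- function(mask, nsym) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(nsym) - 1L)) != 0L)
}

# lowest set bit -> symbol index (alphabet-order first member)
.maskFirst <- function(mask) {
  i <- 1L
  while (bitwAnd(mask, bitwShiftL(1L, i - 1L)) == 0L) i <- i + 1L
  i
}

.vertexNames <- function(tree) {
  n <- length(tree$tip.label)
  inner <- tree$node.label
  if (is.null(inner) || !length(inner) || anyNA(inner) || any(inner == ""))
    inner <- paste0("v", n + seq_len(tree$Nnode))
  c(tree$tip.label, inner)
}

.childrenList <- function(tree) {
  nv <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1L]]] <- c(ch[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  ch
}

.rootNode <- function(tree) length(tree$tip.label) + 1L

.checkBinaryRooted <- function(tree) {
  ch <- .childrenList(tree)
  ndeg <- lengths(ch[(length(tree$tip.label) + 1L):length(ch)])
  if (any(ndeg != 2L))
    stop("tree must be a rooted binary tree (every internal vertex with ",
         "exactly two children); use rootTree() on unrooted input",
         call. = FALSE)
  invisible(TRUE)
}

# postorder vertex sequence (children before parents), root last
.postorderNodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  c(unique(po$edge[, 2L]), .rootNode(tree))
}

.tipsBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ch <- .childrenList(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= ntip) out <- c(out, tree$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  out
}
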