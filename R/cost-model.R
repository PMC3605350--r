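# cost_model module: alphabet, base distance d, powerset distance d_P,
# precomputed lookup tables.

# smallest integer q <= maxDenom with q*x integral for all x
.detectScale <- function(x, maxDenom = 10000L) {
  q <- 1L
  while (q <= maxDenom) {
    if (all(abs(x * q - round(x * q)) < 1e-7)) return(q)
    q <- q + 1L
  }
  stop("cannot represent costs as scaled integers (denominator above ",
       maxDenom, ")", call. = FALSE)
}

.validateCostMatrix <- function(costs, gapExtend, indel) {
  n <- nrow(costs)
  if (ncol(costs) != n) stop("cost matrix must be square", call. = FALSE)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("all costs must be finite and non-negative", call. = FALSE)
  if (any(abs(costs - t(costs)) > 1e-9))
    stop("cost matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(costs)) > 1e-9))
    stop("d(x, x) must be 0 for every symbol", call. = FALSE)
  ind <- costs[n, -n]
  if (any(abs(ind - gapExtend) > 1e-9))
    stop("d(x, ", indel, ") must equal the gap extension cost b (= ",
         gapExtend, ") for every residue x", call. = FALSE)
  invisible(TRUE)
}

#' Construct an edit cost model
#'
#' Builds a \linkS4class{CostModel} either from a uniform substitution cost
#' (\code{subst} for every residue pair) or from an explicit cost matrix over
#' \code{c(alphabet, indel)}.  The indel column of the matrix must be the
#' constant \code{gapExtend}; a model violating this is rejected.
#'
#' @param subst uniform substitution cost between distinct residues (ignored
#'   when \code{costs} is given).
#' @param gapOpen gap opening cost \eqn{a} (\eqn{\ge 0}).
#' @param gapExtend gap extension cost \eqn{b}; also \eqn{d(x, indel)} for
#'   every residue.
#' @param alphabet ordered residue alphabet.
#' @param costs optional full substitution matrix over
#'   \code{c(alphabet, indel)} (indel row/column included).
#' @param indel the indel symbol; always ordered after the residues.
#' @param maxTableSymbols largest total symbol count (indel included) for
#'   which full powerset lookup tables are precomputed.  Larger alphabets
#'   fall back to on-the-fly set-distance computation in
#'   \code{\link{setDistance}} / \code{\link{witnessPair}}; the alignment
#'   kernels require table mode.
#' @return a \code{CostModel}
#' @examples
#' m <- costModel(subst = 1, gapOpen = 3, gapExtend = 1)
#' setDistance("A", c("T", "-"), m)
#' @export
costModel <- function(subst = 1, gapOpen = 0, gapExtend = 1,
                      alphabet = c("A", "C", "G", "T"), costs = NULL,
                      indel = "-", maxTableSymbols = 8L) {
  if (indel %in% alphabet) stop("indel symbol must not be in the alphabet")
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  if (length(gapOpen) != 1L || gapOpen < 0 || !is.finite(gapOpen))
    stop("gapOpen must be a single non-negative finite value")
  nres <- length(alphabet)
  sym <- c(alphabet, indel)
  n <- nres + 1L
  if (is.null(costs)) {
    costs <- matrix(subst, n, n, dimnames = list(sym, sym))
    diag(costs) <- 0
    costs[n, ] <- gapExtend
    costs[, n] <- gapExtend
    costs[n, n] <- 0
  } else {
    costs <- as.matrix(costs)
    if (nrow(costs) != n)
      stop("cost matrix must cover c(alphabet, indel): expected ", n,
           " rows, got ", nrow(costs))
    dimnames(costs) <- list(sym, sym)
    gapExtend <- costs[n, 1L]
  }
  .validateCostMatrix(costs, gapExtend, indel)
  scale <- .detectScale(c(costs, gapOpen, gapExtend))
  icosts <- matrix(as.integer(round(costs * scale)), n, n,
                   dimnames = list(sym, sym))
  tables <- list()
  if (n <= maxTableSymbols) tables <- cpp_build_tables(icosts)
  new("CostModel", alphabet = alphabet, indel = indel, costs = costs,
      gapOpen = gapOpen, gapExtend = gapExtend, scale = as.integer(scale),
      icosts = icosts, tables = tables)
}

#' Read a cost matrix from a TSV file
#'
#' The file has a header row of symbols (the indel symbol included, last)
#' and a square matrix of costs.  The gap opening cost is not part of the
#' matrix and is supplied separately.
#'
#' @param path path to the TSV file.
#' @param gapOpen gap opening cost \eqn{a}.
#' @param indel the indel symbol used in the header.
#' @return a \linkS4class{CostModel}
#' @export
readCostMatrix <- function(path, gapOpen = 0, indel = "-") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(tab)
  sym <- colnames(m)
  if (!indel %in% sym)
    stop("cost matrix header must include the indel symbol '", indel, "'")
  if (sym[length(sym)] != indel) {   # reorder so indel is last
    ord <- c(setdiff(sym, indel), indel)
    m <- m[match(ord, sym), match(ord, sym)]
    sym <- ord
  }
  costModel(alphabet = sym[-length(sym)], costs = m, gapOpen = gapOpen,
            indel = indel)
}

.hasTables <- function(model) length(model@tables) > 0L

.indelMask <- function(model) bitwShiftL(1L, length(model@alphabet))

# character residue-set -> mask
.setToMask <- function(x, model) {
  sym <- c(model@alphabet, model@indel)
  if (is.numeric(x)) return(as.integer(x))
  if (!length(x)) stop("residue sets must be nonempty", call. = FALSE)
  .maskFromIndices(unique(.symbolIndex(x, sym, "residue set")))
}

#' Distance between residue sets under the powerset alphabet
#'
#' \code{setDistance} computes \eqn{d_P(X, Y) = \min_{x \in X, y \in Y}
#' d(x, y)}; \code{witnessPair} returns a member pair realizing it, with
#' ties broken by alphabet order (first on \eqn{x}, then on \eqn{y}).
#'
#' @param X,Y nonempty residue sets, as character vectors of symbols (the
#'   indel symbol allowed).
#' @param model a \linkS4class{CostModel}.
#' @return \code{setDistance}: the minimal cost; \code{witnessPair}: a
#'   character vector \code{c(x, y)}.
#' @examples
#' m <- costModel()
#' setDistance(c("A", "C"), c("C", "G"), m)   # 0, shared member
#' witnessPair("A", c("T", "-"), m)
#' @export
setDistance <- function(X, Y, model) {
  mx <- .setToMask(X, model)
  my <- .setToMask(Y, model)
  if (.hasTables(model)) return(model@tables$dp[mx, my] / model@scale)
  n <- length(model@alphabet) + 1L
  min(model@costs[.maskMembers(mx, n), .maskMembers(my, n)])
}

#' @rdname setDistance
#' @export
witnessPair <- function(X, Y, model) {
  mx <- .setToMask(X, model)
  my <- .setToMask(Y, model)
  sym <- c(model@alphabet, model@indel)
  if (.hasTables(model))
    return(sym[c(model@tables$wx[mx, my], model@tables$wy[mx, my])])
  n <- length(sym)
  mem.x <- .maskMembers(mx, n)
  mem.y <- .maskMembers(my, n)
  best <- Inf
  bx <- by <- NA_integer_
  for (i in mem.x) for (j in mem.y)
    if (model@costs[i, j] < best) { best <- model@costs[i, j]; bx <- i; by <- j }
  sym[c(bx, by)]
}

#' @rdname CostModel-class
#' @param ... ignored
#' @export
setMethod("alphabet", "CostModel", function(x, ...) x@alphabet)

#' @rdname CostModel-class
setMethod("indelSymbol", "CostModel", function(x) x@indel)

#' @rdname CostModel-class
setMethod("substCosts", "CostModel", function(x) x@costs)

#' @rdname CostModel-class
setMethod("gapOpen", "CostModel", function(x) x@gapOpen)

#' @rdname CostModel-class
setMethod("gapExtend", "CostModel", function(x) x@gapExtend)

setMethod("show", "CostModel", function(object) {
  cat("CostModel over {", paste(object@alphabet, collapse = ","),
      "} + '", object@indel, "'\n", sep = "")
  cat("  gap cost G(k) = ", object@gapOpen, " + ", object@gapExtend,
      " * k\n", sep = "")
  cat("  integer scale: ", object@scale,
      if (.hasTables(object)) "; powerset tables precomputed" else
        "; on-the-fly set distances (alphabet above table cap)", "\n",
      sep = "")
})
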