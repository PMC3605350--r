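# rag module: the Reduced Alignment Graph representation and its
# containment semantics.

.newRag <- function(masks, model, groups = NULL) {
  masks <- as.integer(masks)
  if (is.null(groups)) groups <- integer(length(masks))
  new("Rag", masks = masks, symbols = c(model@alphabet, model@indel),
      groups = as.integer(groups))
}

#' Build a RAG from a plain sequence
#'
#' Each residue becomes a singleton column.  With \code{iupac = TRUE},
#' IUPAC ambiguity codes (N, R, Y, ...) are expanded to their residue sets;
#' by default any symbol outside the model's alphabet is an error.
#'
#' @param x a character string over the model's residue alphabet (no indels).
#' @param model a \linkS4class{CostModel}.
#' @param iupac expand IUPAC ambiguity codes to residue sets.
#' @return a \linkS4class{Rag}
#' @examples
#' m <- costModel()
#' ragFromSequence("ATTG", m)
#' ragFromSequence("AR", m, iupac = TRUE)   # [A][AG]
#' @export
ragFromSequence <- function(x, model, iupac = FALSE) {
  chars <- .splitSeq(toupper(x))
  sym <- c(model@alphabet, model@indel)
  if (!iupac) {
    idx <- .encodeSeq(toupper(x), model)
    return(.newRag(bitwShiftL(1L, idx - 1L), model))
  }
  masks <- vapply(chars, function(ch) {
    if (ch %in% model@alphabet)
      return(.maskFromIndices(match(ch, sym)))
    exp <- .IUPAC[[ch]]
    if (is.null(exp) || !all(exp %in% model@alphabet))
      stop("symbol '", ch, "' is neither in the alphabet nor an IUPAC code ",
           "over it", call. = FALSE)
    .maskFromIndices(match(exp, sym))
  }, integer(1), USE.NAMES = FALSE)
  .newRag(masks, model)
}

#' Make a RAG from explicit residue sets
#'
#' @param columns a list of character vectors, one nonempty residue set per
#'   column (the indel symbol allowed).
#' @param model a \linkS4class{CostModel}.
#' @return a \linkS4class{Rag}
#' @examples
#' m <- costModel()
#' rag(list("A", c("T", "-"), c("T", "-"), c("G", "C")), m)
#' @export
rag <- function(columns, model) {
  masks <- vapply(columns, .setToMask, integer(1), model = model)
  .newRag(masks, model)
}

#' Number of (not necessarily distinct) sequence selections in a RAG
#'
#' The product of the column cardinalities: each selection picks one member
#' per column.  Distinct selections may collapse to the same plain sequence
#' after indel removal, so \code{length(containedSequences(A))} can be
#' smaller.
#'
#' For block-grouped columns the group counts as one unit: all-indel, or
#' one residue choice per column.
#'
#' @param A a \linkS4class{Rag}
#' @return a numeric count (empty RAG: 1, the empty product)
#' @export
selectionCount <- function(A) {
  if (!length(A@masks)) return(1)
  nsym <- length(A@symbols)
  ib <- bitwShiftL(1L, nsym - 1L)
  card <- vapply(A@masks, function(m) length(.maskMembers(m, nsym)), integer(1))
  free <- A@groups == 0L
  total <- prod(card[free])
  for (id in unique(A@groups[!free])) {
    w <- A@groups == id
    resid <- vapply(A@masks[w], function(m)
      length(.maskMembers(bitwAnd(m, ib - 1L), nsym)), integer(1))
    total <- total * (prod(resid) + 1)
  }
  total
}

#' Enumerate the plain sequences contained in a RAG
#'
#' Selects one member per column, removes the indels, and returns the set of
#' distinct resulting sequences.  This is an enumeration oracle: it refuses
#' when the selection count exceeds \code{limit}.
#'
#' @param A a \linkS4class{Rag}
#' @param limit maximum number of selections to expand.
#' @return a character vector of distinct contained sequences
#' @examples
#' m <- costModel()
#' A <- rag(list("A", c("T", "-"), c("T", "-"), c("G", "C")), m)
#' sort(containedSequences(A))  # AC AG ATC ATG ATTC ATTG
#' @export
containedSequences <- function(A, limit = 10000) {
  if (selectionCount(A) > limit)
    stop("RAG has ", selectionCount(A), " selections, above the ",
         "enumeration limit (", limit, ")", call. = FALSE)
  nsym <- length(A@symbols)
  if (!length(A@masks)) return("")
  indel <- A@symbols[nsym]
  ib <- bitwShiftL(1L, nsym - 1L)
  # units: an ordinary column -> its member symbols; an atomic block -> the
  # all-indel selection plus every all-residue combination
  units <- list()
  k <- 1L
  while (k <= length(A@masks)) {
    if (A@groups[k] == 0L) {
      opts <- A@symbols[.maskMembers(A@masks[k], nsym)]
      opts[opts == indel] <- ""
      units[[length(units) + 1L]] <- unique(opts)
      k <- k + 1L
    } else {
      id <- A@groups[k]
      w <- which(A@groups == id)
      cols <- lapply(A@masks[w], function(m)
        A@symbols[.maskMembers(bitwAnd(m, ib - 1L), nsym)])
      combos <- apply(expand.grid(cols, stringsAsFactors = FALSE), 1L,
                      paste, collapse = "")
      units[[length(units) + 1L]] <- unique(c("", combos))
      k <- max(w) + 1L
    }
  }
  grid <- expand.grid(units, stringsAsFactors = FALSE)
  unique(apply(grid, 1L, paste, collapse = ""))
}

#' Drop pure-indel columns from a RAG
#'
#' Removes the columns whose set is exactly \{indel\}; all other columns are
#' preserved in order.  Contained sequences are unchanged.
#'
#' @param A a \linkS4class{Rag}
#' @return a \linkS4class{Rag}
#' @export
stripIndelColumns <- function(A) {
  ib <- bitwShiftL(1L, length(A@symbols) - 1L)
  keep <- A@masks != ib
  new("Rag", masks = A@masks[keep], symbols = A@symbols,
      groups = A@groups[keep])
}

#' @rdname Rag-class
#' @param x a \code{Rag}
#' @export
setMethod("ragMasks", "Rag", function(x) x@masks)

#' Block-group ids of a RAG's columns
#'
#' @param A a \linkS4class{Rag}
#' @return integer vector, 0 for ordinary columns, shared nonzero ids for
#'   the columns of an atomic optional gap block
#' @export
ragGroups <- function(A) A@groups

#' @rdname Rag-class
#' @param ... ignored
#' @export
setMethod("alphabet", "Rag", function(x, ...) x@symbols)

#' @rdname Rag-class
#' @export
setMethod("length", "Rag", function(x) length(x@masks))

#' Bracketed text rendering of a RAG
#'
#' @param A a \linkS4class{Rag}
#' @return a string like \code{"[A][T-][T-][GC]"}
#' @export
ragToString <- function(A) {
  nsym <- length(A@symbols)
  if (!length(A@masks)) return("")
  paste(vapply(A@masks, function(m)
    paste0("[", paste(A@symbols[.maskMembers(m, nsym)], collapse = ""), "]"),
    character(1)), collapse = "")
}

setMethod("show", "Rag", function(object) {
  cat("Rag with ", length(object@masks), " column(s): ",
      ragToString(object), "\n", sep = "")
})
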