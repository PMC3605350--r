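# cli_io module: FASTA and Newick readers/writers. The command-line surface
# is a thin Rscript over these functions (inst/scripts/affinedo).

#' Read sequences from a FASTA file
#'
#' Order-preserving, uppercase-normalized; header names are the first
#' whitespace-delimited token.  CRLF line endings are handled by the
#' underlying parser.  Symbols are validated later, against the cost
#' model's alphabet (optionally through IUPAC expansion, see
#' \code{\link{ragFromSequence}}).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences
#' @export
readFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (e.g. a vertex labeling).
#' @param path output path.
#' @return invisibly, the path
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tree from a Newick file
#'
#' Returns the tree as parsed; a rooted binary tree passes
#' \code{\link{rootTree}} unchanged, a basal trifurcation (ape's unrooted
#' form) can be rooted on any edge with it.  When \code{seqs} is given the
#' tip labels are checked against the sequence names and mismatches are
#' reported by name.
#'
#' @param path path to a Newick file.
#' @param seqs optional named sequences to validate tip labels against.
#' @return a \code{phylo}
#' @export
readNewick <- function(path, seqs = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (!is.null(seqs)) {
    miss <- setdiff(tr$tip.label, names(seqs))
    extra <- setdiff(names(seqs), tr$tip.label)
    if (length(miss) || length(extra))
      stop("tree/sequence name mismatch",
           if (length(miss)) paste0("; tips without sequences: ",
                                    paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; sequences without tips: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
  }
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree a \code{phylo}.
#' @param path output path.
#' @return invisibly, the path
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
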