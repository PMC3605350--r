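#' @importFrom Biostrings alphabet
NULL

#' @rdname CostModel-class
#' @param object,x a \code{CostModel}
#' @export
setGeneric("indelSymbol", function(x) standardGeneric("indelSymbol"))

#' @rdname CostModel-class
#' @export
setGeneric("substCosts", function(x) standardGeneric("substCosts"))

#' @rdname CostModel-class
#' @export
setGeneric("gapOpen", function(x) standardGeneric("gapOpen"))

#' @rdname CostModel-class
#' @export
setGeneric("gapExtend", function(x) standardGeneric("gapExtend"))

#' @rdname Rag-class
#' @export
setGeneric("ragMasks", function(x) standardGeneric("ragMasks"))

#' @rdname RagAlignment-class
#' @export
setGeneric("alignmentCost", function(x) standardGeneric("alignmentCost"))

#' @rdname RagAlignment-class
#' @export
setGeneric("alignedRags", function(x) standardGeneric("alignedRags"))

#' @rdname RagAlignment-class
#' @export
setGeneric("alignmentTrace", function(x) standardGeneric("alignmentTrace"))

#' @rdname DoTraversal-class
#' @export
setGeneric("traversalCost", function(x) standardGeneric("traversalCost"))

#' @rdname DoTraversal-class
#' @export
setGeneric("vertexRags", function(x) standardGeneric("vertexRags"))
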