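#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("obsIds", function(x) standardGeneric("obsIds"))

#' @export
setGeneric("obsKind", function(x) standardGeneric("obsKind"))

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("setInfo", function(x) standardGeneric("setInfo"))

#' @export
setGeneric("miaTable", function(x) standardGeneric("miaTable"))

#' @export
setGeneric("miaBackground", function(x) standardGeneric("miaBackground"))

#' @export
setGeneric("miaOverlaps", function(x) standardGeneric("miaOverlaps"))

#' @export
setGeneric("lrPairs", function(x) standardGeneric("lrPairs"))

#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @export
setGeneric("qcSummary", function(x) standardGeneric("qcSummary"))

#' @export
setGeneric("droppedIds", function(x, rule) standardGeneric("droppedIds"))
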