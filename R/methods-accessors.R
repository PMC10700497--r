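#' Accessors for follimap S4 classes
#'
#' @param x A follimap object.
#' @param object A follimap object (show methods).
#' @param rule For [droppedIds()], the QC rule name.
#' @name accessors
NULL

## ---- CountMatrix ----

#' @describeIn accessors Sparse counts of a [CountMatrix-class].
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @describeIn accessors Gene symbols (rows).
#' @export
setMethod("geneIds", "CountMatrix", function(x) rownames(x@counts))

#' @describeIn accessors Observation barcodes (columns).
#' @export
setMethod("obsIds", "CountMatrix", function(x) colnames(x@counts))

#' @describeIn accessors Observation kind, "cell" or "spot".
#' @export
setMethod("obsKind", "CountMatrix", function(x) x@obsKind)

setMethod("dim", "CountMatrix", function(x) dim(x@counts))

setMethod("show", "CountMatrix", function(object) {
    cat(sprintf("CountMatrix: %d genes x %d %ss, %d nonzero entries\n",
                nrow(object@counts), ncol(object@counts), object@obsKind,
                length(object@counts@x)))
})

## ---- ExpressionMatrix ----

#' @describeIn accessors Log-normalized values of an
#'   [ExpressionMatrix-class].
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn accessors Normalization scale factor S.
#' @export
setMethod("scaleFactor", "ExpressionMatrix", function(x) x@scaleFactor)

#' @describeIn accessors Gene symbols of an ExpressionMatrix.
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn accessors Barcodes of an ExpressionMatrix.
#' @export
setMethod("obsIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn accessors Observation kind of an ExpressionMatrix.
#' @export
setMethod("obsKind", "ExpressionMatrix", function(x) x@obsKind)

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf(
        "ExpressionMatrix: %d genes x %d %ss, ln(1 + count/total * S), S = %g\n",
        nrow(object@values), ncol(object@values), object@obsKind,
        object@scaleFactor))
})

## ---- QCReport ----

#' @describeIn accessors Named per-rule drop counters plus totals.
#' @export
setMethod("qcSummary", "QCReport", function(x)
    c(n_in = x@nIn, x@nDropped, n_out = x@nOut))

#' @describeIn accessors Identifiers removed by one rule.
#' @export
setMethod("droppedIds", "QCReport", function(x, rule) {
    if (!rule %in% names(x@dropped))
        stop("unknown QC rule '", rule, "'; rules: ",
             paste(names(x@dropped), collapse = ", "))
    x@dropped[[rule]]
})

setMethod("show", "QCReport", function(object) {
    cat(sprintf("QCReport: %d in, %d out\n", object@nIn, object@nOut))
    for (r in names(object@nDropped))
        cat(sprintf("  %-12s dropped %d\n", r, object@nDropped[[r]]))
})

## ---- LRDatabase ----

#' @describeIn accessors Pair table of an [LRDatabase-class].
#' @export
setMethod("lrPairs", "LRDatabase", function(x) x@pairs)

setMethod("length", "LRDatabase", function(x) nrow(x@pairs))

setMethod("show", "LRDatabase", function(object) {
    cat(sprintf("LRDatabase: %d ligand-receptor pairs (%d dropped unmapped)\n",
                nrow(object@pairs), object@nDroppedUnmapped))
})

## ---- GeneSetCollection ----

#' @describeIn accessors Named list of gene sets.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn accessors Per-set provenance table.
#' @export
setMethod("setInfo", "GeneSetCollection", function(x) x@info)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n",
                length(object@sets),
                paste(lengths(object@sets), collapse = ", ")))
})

## ---- MIAMap ----

#' @describeIn accessors Long-format enrichment/depletion table.
#' @export
setMethod("miaTable", "MIAMap", function(x) x@table)

#' @describeIn accessors Gene universe used as hypergeometric background.
#' @export
setMethod("miaBackground", "MIAMap", function(x) x@background)

#' @describeIn accessors Overlapping genes per (type, region) pair.
#' @export
setMethod("miaOverlaps", "MIAMap", function(x) x@overlaps)

setMethod("show", "MIAMap", function(object) {
    cat(sprintf("MIAMap: %d cell types x %d regions, background %d genes\n",
                length(unique(object@table$type)),
                length(unique(object@table$region)),
                length(object@background)))
})

## ---- InteractionTable ----

#' @describeIn accessors Interaction records of an
#'   [InteractionTable-class].
#' @export
setMethod("interactions", "InteractionTable", function(x) x@records)

setMethod("show", "InteractionTable", function(object) {
    r <- object@records
    cat(sprintf(
        "InteractionTable: %d records (%d pairs, %d time points), B = %d\n",
        nrow(r), length(unique(r$pair_id)), length(unique(r$time_point)),
        if (nrow(r)) r$n_perm[1] else 0L))
})
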