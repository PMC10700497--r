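#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t
#' @importClassesFrom Matrix dgCMatrix
NULL

#' CountMatrix: sparse gene x observation UMI counts
#'
#' Container for a sparse matrix of non-negative integer UMI counts with
#' genes as rows and observations (cells or spots) as columns. Gene symbols
#' and observation barcodes are carried as dimnames and must be unique.
#'
#' @slot counts A \code{dgCMatrix} of non-negative integral counts,
#'   genes x observations, with unique dimnames.
#' @slot obsKind Either \code{"cell"} or \code{"spot"}.
#'
#' @seealso [CountMatrix()] for the constructor, [readCountMatrix()] and
#'   [writeCountMatrix()] for the on-disk MatrixMarket representation.
#' @exportClass CountMatrix
setClass("CountMatrix",
    representation(counts = "dgCMatrix", obsKind = "character"))

setValidity("CountMatrix", function(object) {
    m <- object@counts
    msg <- character()
    if (!object@obsKind %in% c("cell", "spot"))
        msg <- c(msg, "obsKind must be 'cell' or 'spot'")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "counts must carry gene (row) and barcode (column) names")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "duplicate gene identifiers")
        if (anyDuplicated(colnames(m)))
            msg <- c(msg, "duplicate observation barcodes")
    }
    if (length(m@x)) {
        if (any(m@x < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(m@x != round(m@x)))
            msg <- c(msg, "counts must be integral")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts
#'   (genes x observations) with unique row and column names.
#' @param obsKind \code{"cell"} or \code{"spot"}.
#' @return A [CountMatrix-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 2L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("b1", "b2")))
#' CountMatrix(m, "cell")
#' @export
CountMatrix <- function(counts, obsKind = c("cell", "spot")) {
    obsKind <- match.arg(obsKind)
    counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    new("CountMatrix", counts = counts, obsKind = obsKind)
}

#' ExpressionMatrix: log-normalized expression values
#'
#' Log-normalized expression with normalization metadata: each observation's
#' counts are divided by the observation total, multiplied by a scale factor
#' S, and transformed with log(1 + x). Zero counts map to exactly zero, so
#' sparsity is preserved.
#'
#' @slot values A \code{dgCMatrix} of non-negative log-normalized values.
#' @slot scaleFactor The scale factor S applied before the log transform.
#' @slot logBase Base of the logarithm (the natural base, \code{exp(1)}).
#' @slot obsKind \code{"cell"} or \code{"spot"}.
#' @seealso [logNormalize()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "dgCMatrix", scaleFactor = "numeric",
                   logBase = "numeric", obsKind = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@values@x) && any(object@values@x < 0))
        msg <- c(msg, "log-normalized values must be non-negative")
    if (length(object@scaleFactor) != 1L || object@scaleFactor <= 0)
        msg <- c(msg, "scaleFactor must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' QCReport: per-rule accounting of a filtering step
#'
#' Records, for one QC operation, how many observations (or genes) entered,
#' how many each rule removed, and how many survived. An item is attributed
#' to the first rule (in the documented order) that removes it, so the
#' counters always conserve: \code{nIn - sum(nDropped) == nOut}.
#'
#' @slot nIn Number of items entering the filter.
#' @slot nOut Number of items surviving.
#' @slot nDropped Named integer vector, one counter per rule, in application
#'   order.
#' @slot dropped Named list of character vectors: the identifiers each rule
#'   removed.
#' @exportClass QCReport
setClass("QCReport",
    representation(nIn = "integer", nOut = "integer",
                   nDropped = "integer", dropped = "list"))

setValidity("QCReport", function(object) {
    if (object@nIn - sum(object@nDropped) != object@nOut)
        return("counters do not conserve: nIn - sum(nDropped) != nOut")
    if (!identical(names(object@nDropped), names(object@dropped)))
        return("nDropped and dropped must share rule names")
    if (!all(lengths(object@dropped) == object@nDropped))
        return("per-rule identifier lists inconsistent with counters")
    TRUE
})

QCReport <- function(nIn, dropped, nOut) {
    new("QCReport", nIn = as.integer(nIn), nOut = as.integer(nOut),
        nDropped = vapply(dropped, length, 1L), dropped = dropped)
}

#' LRDatabase: ligand-receptor pair table
#'
#' A table of candidate ligand-receptor pairs, optionally passed through an
#' ortholog map at read time. Pairs whose genes could not be mapped are
#' dropped and counted, never silently invented.
#'
#' @slot pairs data.frame with columns \code{pair_id}, \code{ligand},
#'   \code{receptor}, \code{source_annotation}.
#' @slot nDroppedUnmapped Number of pairs dropped because a gene had no
#'   ortholog entry.
#' @slot droppedPairs pair_ids of the dropped pairs.
#' @seealso [readLRDatabase()]
#' @exportClass LRDatabase
setClass("LRDatabase",
    representation(pairs = "data.frame", nDroppedUnmapped = "integer",
                   droppedPairs = "character"))

setValidity("LRDatabase", function(object) {
    p <- object@pairs
    need <- c("pair_id", "ligand", "receptor", "source_annotation")
    if (!all(need %in% names(p)))
        return(paste("pairs must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(p$pair_id))
        return("pair_id must be unique")
    if (any(!nzchar(p$ligand)) || any(!nzchar(p$receptor)))
        return("ligand and receptor genes must be non-empty")
    TRUE
})

LRDatabase <- function(pairs, nDroppedUnmapped = 0L,
                       droppedPairs = character()) {
    new("LRDatabase", pairs = pairs,
        nDroppedUnmapped = as.integer(nDroppedUnmapped),
        droppedPairs = droppedPairs)
}

#' GeneSetCollection: named marker gene sets with provenance
#'
#' Named gene sets (one per cell type or spatial region) together with the
#' provenance of each set: which modality and test produced it and at what
#' threshold. Feeds the MIA map.
#'
#' @slot sets Named list of character vectors of gene symbols.
#' @slot info data.frame with one row per set: \code{set}, \code{modality},
#'   \code{test}, \code{p_threshold}, \code{adjusted}, \code{logfc_min},
#'   \code{n_genes}.
#' @seealso [buildGeneSets()], [miaMap()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    representation(sets = "list", info = "data.frame"))

setValidity("GeneSetCollection", function(object) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        return("sets must be uniquely named")
    if (nrow(object@info) && !identical(object@info$set, names(object@sets)))
        return("info rows must match set names, in order")
    TRUE
})

#' MIAMap: hypergeometric enrichment/depletion map
#'
#' The multimodal intersection analysis result: for every (cell-type set,
#' region set) pair, the overlap k, set sizes m and n, background size N,
#' the upper-tail hypergeometric P, the enrichment score -log10(P) and the
#' depletion score -log10(1 - P) (computed from the directly summed lower
#' tail, never as 1 - P).
#'
#' @slot table Long-format data.frame with columns \code{type},
#'   \code{region}, \code{k}, \code{m}, \code{n}, \code{N}, \code{p},
#'   \code{enrichment}, \code{depletion}.
#' @slot background Character vector: the gene universe used.
#' @slot overlaps Named list (\code{"type|region"}) of overlapping gene
#'   vectors.
#' @seealso [miaMap()], [miaPair()]
#' @exportClass MIAMap
setClass("MIAMap",
    representation(table = "data.frame", background = "character",
                   overlaps = "list"))

setValidity("MIAMap", function(object) {
    tb <- object@table
    if (!nrow(tb)) return(TRUE)
    if (any(tb$k > pmin(tb$m, tb$n)) || any(tb$m > tb$N) || any(tb$n > tb$N))
        return("k <= min(m, n) <= N violated")
    if (any(tb$p < 0 | tb$p > 1))
        return("p must lie in [0, 1]")
    if (any(tb$enrichment < 0) || any(tb$depletion < 0))
        return("scores must be non-negative")
    TRUE
})

#' InteractionTable: ligand-receptor interaction scores with permutation p
#'
#' One record per evaluable (pair, sender type, receiver type, time point)
#' combination: the observed interaction score, a summary of the permutation
#' null, the empirical p and its BH adjustment.
#'
#' @slot records data.frame with columns \code{pair_id}, \code{ligand},
#'   \code{receptor}, \code{sender}, \code{receiver}, \code{time_point},
#'   \code{score}, \code{null_mean}, \code{null_q95}, \code{null_q99},
#'   \code{n_perm}, \code{p_empirical}, \code{p_adjusted}.
#' @slot config The permutation configuration used (list).
#' @seealso [interactionTable()], [significantInteractionCounts()]
#' @exportClass InteractionTable
setClass("InteractionTable",
    representation(records = "data.frame", config = "list"))

setValidity("InteractionTable", function(object) {
    r <- object@records
    if (nrow(r) && any(r$p_empirical < 0 | r$p_empirical > 1))
        return("p_empirical must lie in [0, 1]")
    TRUE
})
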