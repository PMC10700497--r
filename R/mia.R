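#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing an overlap of at least \code{k} genes between a
#' set of size \code{m} and a set of size \code{n} drawn from a background
#' of \code{N} genes, under the hypergeometric null. Both tails are
#' computed directly in log space (the lower tail by direct summation,
#' never as 1 - p), so extreme enrichment and extreme depletion are both
#' representable.
#'
#' @param k Overlap size, \code{0 <= k <= min(m, n)}.
#' @param m,n Set sizes, each \code{<= N}.
#' @param N Background (gene universe) size.
#' @param log10p Return log10 of the probability instead.
#' @return \code{P(X >= k)} (or its log10). Vectorized over \code{k}.
#' @export
hypergeomUpperTail <- function(k, m, n, N, log10p = FALSE) {
    if (any(c(k, m, n, N) != round(c(k, m, n, N))))
        stop("k, m, n, N must be integers")
    if (any(m > N) || any(n > N))
        stop("set sizes m, n must not exceed the background N")
    if (any(k < 0) || any(k > pmin(m, n)))
        stop("k must lie in [0, min(m, n)]")
    lp <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE,
                        log.p = TRUE)
    lp[k == 0] <- 0  # P(X >= 0) = 1
    if (log10p) lp / log(10) else exp(lp)
}

# log10 of the complement P(X <= k - 1), summed directly on the lower tail.
.hypergeomLowerLog10 <- function(k, m, n, N) {
    lo <- stats::phyper(k - 1, m, N - m, n, lower.tail = TRUE, log.p = TRUE)
    lo[k == 0] <- -Inf  # P(X <= -1) = 0
    lo / log(10)
}

#' Enrichment/depletion record for one pair of gene sets
#'
#' Computes the multimodal-intersection record for one (cell-type set,
#' region set) pair against a background: the overlap \code{k}, set sizes
#' \code{m} and \code{n} (after dropping genes absent from the background,
#' which are counted and warned about, never added to the background),
#' background size \code{N}, the upper-tail hypergeometric
#' \code{p = P(X >= k)}, the enrichment score \code{-log10(p)} and the
#' depletion score \code{-log10(1 - p)} computed from the directly summed
#' lower tail (1 - p underflows exactly where depletion is strongest).
#'
#' @param setA,setB Character vectors of gene symbols.
#' @param background Character vector: the gene universe.
#' @param scoreCap Upper cap applied to both scores (default 300, a
#'   plotting-friendly ceiling).
#' @return A one-row data.frame with columns \code{k}, \code{m}, \code{n},
#'   \code{N}, \code{p}, \code{enrichment}, \code{depletion},
#'   \code{n_outside_background}; the overlapping genes are attached as
#'   \code{attr(, "overlap")}.
#' @export
miaPair <- function(setA, setB, background, scoreCap = 300) {
    if (!length(background)) stop("background must be non-empty")
    background <- unique(background)
    setA <- unique(setA); setB <- unique(setB)
    outside <- length(setdiff(setA, background)) +
        length(setdiff(setB, background))
    if (outside > 0)
        warning(outside, " gene(s) outside the background dropped from ",
                "the sets")
    A <- intersect(setA, background)
    B <- intersect(setB, background)
    k <- length(intersect(A, B))
    m <- length(A); n <- length(B); N <- length(background)
    upLog10 <- hypergeomUpperTail(k, m, n, N, log10p = TRUE)
    loLog10 <- .hypergeomLowerLog10(k, m, n, N)
    rec <- data.frame(k = k, m = m, n = n, N = N, p = 10^upLog10,
                      enrichment = min(-upLog10, scoreCap),
                      depletion = min(-loLog10, scoreCap),
                      n_outside_background = outside)
    attr(rec, "overlap") <- sort(intersect(A, B))
    rec
}

#' The MIA map: all cell-type sets against all region sets
#'
#' Computes [miaPair()] for every combination of a cell-type gene set and a
#' region gene set over a common background, yielding the long-format
#' enrichment/depletion map. The default background is the intersection of
#' the two modalities' post-QC gene universes ("all genes as the
#' background" is only well-defined on genes both modalities could have
#' contributed); union and custom backgrounds are selectable.
#'
#' @param typeSets A [GeneSetCollection-class] (e.g. scRNA cell types).
#' @param regionSets A [GeneSetCollection-class] (e.g. ST regions).
#' @param universeA,universeB The post-QC gene universes of the two
#'   modalities (required for the intersection / union modes).
#' @param backgroundMode \code{"intersection"} (default), \code{"union"}
#'   or \code{"custom"}.
#' @param background Character vector, used when
#'   \code{backgroundMode = "custom"}.
#' @param scoreCap Passed to [miaPair()].
#' @param allowEmpty Permit empty member sets (default: error, since an
#'   empty set always yields k = 0 and a maximal depletion score).
#' @return A [MIAMap-class].
#' @export
miaMap <- function(typeSets, regionSets, universeA = NULL, universeB = NULL,
                   backgroundMode = c("intersection", "union", "custom"),
                   background = NULL, scoreCap = 300, allowEmpty = FALSE) {
    backgroundMode <- match.arg(backgroundMode)
    stopifnot(is(typeSets, "GeneSetCollection"),
              is(regionSets, "GeneSetCollection"))
    if (!length(typeSets@sets) || !length(regionSets@sets))
        stop("both gene set collections must be non-empty")
    empty <- lengths(c(geneSets(typeSets), geneSets(regionSets))) == 0
    if (any(empty) && !allowEmpty)
        stop("empty gene set(s) may not enter the MIA map without ",
             "allowEmpty = TRUE: ",
             paste(names(empty)[empty], collapse = ", "))
    bg <- switch(backgroundMode,
        intersection = {
            if (is.null(universeA) || is.null(universeB))
                stop("intersection mode needs universeA and universeB")
            intersect(universeA, universeB)
        },
        union = {
            if (is.null(universeA) || is.null(universeB))
                stop("union mode needs universeA and universeB")
            union(universeA, universeB)
        },
        custom = {
            if (is.null(background))
                stop("custom mode needs an explicit background")
            unique(background)
        })
    if (!length(bg)) stop("background is empty")
    allSets <- c(geneSets(typeSets), geneSets(regionSets))
    tooBig <- lengths(allSets) > length(bg)
    if (any(tooBig))
        stop("background (", length(bg), " genes) is smaller than set(s): ",
             paste(names(allSets)[tooBig], collapse = ", "))
    rows <- list(); overlaps <- list()
    for (ty in names(typeSets@sets)) {
        for (rg in names(regionSets@sets)) {
            rec <- miaPair(typeSets@sets[[ty]], regionSets@sets[[rg]],
                           bg, scoreCap)
            key <- paste(ty, rg, sep = "|")
            overlaps[[key]] <- attr(rec, "overlap")
            rows[[key]] <- cbind(data.frame(type = ty, region = rg,
                                            stringsAsFactors = FALSE), rec)
        }
    }
    tb <- do.call(rbind, rows)
    rownames(tb) <- NULL
    new("MIAMap", table = tb, background = bg, overlaps = overlaps)
}

#' Write a MIA map as long-format TSV
#'
#' Columns: type, region, k, m, n, N, p, enrichment, depletion — the
#' heatmap-ready long format (set sizes m and n mirror the bracketed counts
#' shown beside MIA heatmap axes).
#'
#' @param map A [MIAMap-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMIAMap <- function(map, path) {
    writeResultTSV(miaTable(map)[c("type", "region", "k", "m", "n", "N",
                                   "p", "enrichment", "depletion")], path)
}
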