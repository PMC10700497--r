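#' Quality-control parameters
#'
#' Thresholds for cell, gene and spot filtering. All printed thresholds are
#' applied with strict inequality exactly as stated (mitochondrial fraction
#' > 10\%, UMIs < 200 or > 10,000, genes expressed in fewer than three
#' cells), so boundary values survive. The hemoglobin cutoff and the spot
#' minima are artifact defaults: the source analyses state them only
#' qualitatively ("high levels of hemoglobin-encoding genes", "extremely low
#' UMIs or genes").
#'
#' @param mitoMax Drop cells with mitochondrial count fraction strictly
#'   above this (default 0.10).
#' @param umiMin Drop cells with total UMIs strictly below this (200).
#' @param umiMax Drop cells with total UMIs strictly above this (10,000).
#' @param hbMax Drop cells with hemoglobin count fraction strictly above
#'   this (default 0.01).
#' @param minCellsPerGene Keep genes with nonzero counts in at least this
#'   many cells (3).
#' @param expectedDoubletRate Fraction of cells per sample (time point)
#'   removed as doublets by score ranking (0.06).
#' @param spotUmiMin,spotGeneMin Spot minima (defaults 250 UMIs, 100 genes).
#' @param dropMitoRiboGenesInSpots Remove mitochondrial and ribosomal genes
#'   from spot matrices (default TRUE).
#' @param excludeSpotLabels Region labels excluded outright (stand-in for
#'   morphology-based non-tissue exclusion).
#' @return A validated list of class \code{QCParams}.
#' @export
qcParams <- function(mitoMax = 0.10, umiMin = 200L, umiMax = 10000L,
                     hbMax = 0.01, minCellsPerGene = 3L,
                     expectedDoubletRate = 0.06,
                     spotUmiMin = 250L, spotGeneMin = 100L,
                     dropMitoRiboGenesInSpots = TRUE,
                     excludeSpotLabels = character()) {
    if (umiMin >= umiMax) stop("umiMin must be < umiMax")
    for (r in c(mitoMax, hbMax, expectedDoubletRate))
        if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
    p <- list(mitoMax = mitoMax, umiMin = umiMin, umiMax = umiMax,
              hbMax = hbMax, minCellsPerGene = as.integer(minCellsPerGene),
              expectedDoubletRate = expectedDoubletRate,
              spotUmiMin = spotUmiMin, spotGeneMin = spotGeneMin,
              dropMitoRiboGenesInSpots = dropMitoRiboGenesInSpots,
              excludeSpotLabels = excludeSpotLabels)
    class(p) <- "QCParams"
    p
}

#' Per-observation QC statistics from a count matrix
#'
#' Computes total UMIs, detected genes and mitochondrial / hemoglobin count
#' fractions directly from the counts. QC filters always use these derived
#' statistics, never stale annotation columns.
#'
#' @param m A [CountMatrix-class].
#' @param mitoGenes,hbGenes Gene symbols of the mitochondrial and
#'   hemoglobin classes (absent symbols are ignored).
#' @return data.frame with columns \code{total_umi}, \code{n_genes},
#'   \code{mito_fraction}, \code{hb_fraction}, one row per observation.
#' @export
computeObsStats <- function(m, mitoGenes = character(),
                            hbGenes = character()) {
    cm <- counts(m)
    tot <- Matrix::colSums(cm)
    frac <- function(genes) {
        g <- intersect(genes, rownames(cm))
        as.numeric(Matrix::colSums(cm[g, , drop = FALSE])) / pmax(tot, 1)
    }
    data.frame(total_umi = as.integer(tot),
               n_genes = as.integer(Matrix::colSums(cm > 0)),
               mito_fraction = frac(mitoGenes),
               hb_fraction = frac(hbGenes),
               row.names = NULL)
}

# First-rule attribution: each id is charged to the first rule (in the
# given order) whose predicate removes it.
.attributeDrops <- function(ids, flags) {
    dropped <- list()
    taken <- rep(FALSE, length(ids))
    for (rule in names(flags)) {
        hit <- flags[[rule]] & !taken
        dropped[[rule]] <- ids[hit]
        taken <- taken | flags[[rule]]
    }
    list(keep = ids[!taken], dropped = dropped)
}

#' Filter low-quality cells
#'
#' Drops cells whose mitochondrial fraction exceeds \code{mitoMax}, whose
#' total UMIs fall below \code{umiMin} or above \code{umiMax}, or whose
#' hemoglobin fraction exceeds \code{hbMax} (all strict inequalities).
#' Statistics are recomputed from the matrix. Rule order for attribution:
#' mito, umi_min, umi_max, hb.
#'
#' @param m A [CountMatrix-class] with \code{obsKind == "cell"}.
#' @param obs The observation table annotating \code{m}.
#' @param params A [qcParams()] object.
#' @param mitoGenes,hbGenes Gene class symbol lists (must be disjoint).
#' @return list with elements \code{counts}, \code{obs} (both filtered,
#'   obs carries refreshed QC statistics) and \code{report}
#'   ([QCReport-class]).
#' @export
qcCells <- function(m, obs, params = qcParams(), mitoGenes = character(),
                    hbGenes = character()) {
    stopifnot(is(m, "CountMatrix"))
    if (length(intersect(mitoGenes, hbGenes)))
        stop("mitochondrial and hemoglobin gene lists must be disjoint")
    obs <- validateObsTable(obs, obsKind(m), obsIds(m))
    obs <- obs[match(obsIds(m), obs$obs_id), , drop = FALSE]
    st <- computeObsStats(m, mitoGenes, hbGenes)
    for (col in names(st)) obs[[col]] <- st[[col]]
    flags <- list(mito = st$mito_fraction > params$mitoMax,
                  umi_min = st$total_umi < params$umiMin,
                  umi_max = st$total_umi > params$umiMax,
                  hb = st$hb_fraction > params$hbMax)
    att <- .attributeDrops(obsIds(m), flags)
    if (!length(att$keep))
        stop("no cells survive QC; review thresholds in qcParams()")
    report <- QCReport(ncol(m), att$dropped, length(att$keep))
    list(counts = CountMatrix(counts(m)[, att$keep, drop = FALSE],
                              obsKind(m)),
         obs = obs[obs$obs_id %in% att$keep, ],
         report = report)
}

#' Filter rarely expressed genes
#'
#' Keeps genes with nonzero counts in at least \code{minCellsPerGene}
#' observations ("expressed in less than three cells" are removed, strict).
#'
#' @inheritParams qcCells
#' @return list with \code{counts} and \code{report} (items are genes).
#' @export
qcGenes <- function(m, params = qcParams()) {
    stopifnot(is(m, "CountMatrix"))
    nCells <- Matrix::rowSums(counts(m) > 0)
    flags <- list(min_cells = nCells < params$minCellsPerGene)
    att <- .attributeDrops(geneIds(m), flags)
    if (!length(att$keep))
        stop("no genes survive QC; review minCellsPerGene")
    list(counts = CountMatrix(counts(m)[att$keep, , drop = FALSE],
                              obsKind(m)),
         report = QCReport(nrow(m), att$dropped, length(att$keep)))
}

#' Remove putative doublets by score ranking
#'
#' Within each sample (time point), removes the top
#' \code{expectedDoubletRate} fraction of cells ranked by
#' \code{doublet_score} (fraction rounded to the nearest integer count;
#' ties broken by barcode lexicographic order, so the result is
#' deterministic). Scores come from the observation table: either the
#' synthetic truth or an external doublet caller's output.
#'
#' @param obs Observation table with \code{obs_id}, \code{time_point} and
#'   \code{doublet_score} columns.
#' @param params A [qcParams()] object.
#' @return list with \code{kept} (surviving barcodes, input order) and
#'   \code{report}.
#' @export
qcDoublets <- function(obs, params = qcParams()) {
    if (is.null(obs$doublet_score) || anyNA(obs$doublet_score))
        stop("doublet_score missing: supply a doublet score column ",
             "for every cell")
    tp <- if (is.null(obs$time_point)) rep("all", nrow(obs)) else
        as.character(obs$time_point)
    removed <- character()
    for (s in unique(tp)) {
        idx <- which(tp == s)
        nd <- round(params$expectedDoubletRate * length(idx))
        if (nd > 0) {
            o <- idx[order(-obs$doublet_score[idx], obs$obs_id[idx])]
            removed <- c(removed, obs$obs_id[o[seq_len(nd)]])
        }
    }
    kept <- setdiff(obs$obs_id, removed)
    if (!length(kept))
        stop("no cells survive doublet removal; review expectedDoubletRate")
    list(kept = kept,
         report = QCReport(nrow(obs), list(doublet = removed), length(kept)))
}

#' Filter spatial spots and contaminant gene classes
#'
#' Order of operations: spots with an excluded region label are removed
#' first (the stand-in for morphology-based non-tissue exclusion), then
#' mitochondrial and ribosomal genes are dropped, then spots failing the
#' UMI / detected-gene minima (computed on the remaining gene universe, so
#' the filter is idempotent) are removed.
#'
#' @inheritParams qcCells
#' @param riboGenes Ribosomal gene symbols.
#' @return list with \code{counts}, \code{obs}, \code{report} (spots) and
#'   \code{removedGenes}.
#' @export
qcSpots <- function(m, obs, params = qcParams(), mitoGenes = character(),
                    riboGenes = character()) {
    stopifnot(is(m, "CountMatrix"), obsKind(m) == "spot")
    obs <- validateObsTable(obs, "spot", obsIds(m))
    obs <- obs[match(obsIds(m), obs$obs_id), , drop = FALSE]
    excluded <- !is.null(obs$group_label) &
        obs$group_label %in% params$excludeSpotLabels
    removedGenes <- character()
    cm <- counts(m)
    if (params$dropMitoRiboGenesInSpots) {
        removedGenes <- intersect(c(mitoGenes, riboGenes), rownames(cm))
        cm <- cm[setdiff(rownames(cm), removedGenes), , drop = FALSE]
    }
    tot <- Matrix::colSums(cm)
    ng <- Matrix::colSums(cm > 0)
    flags <- list(excluded_label = excluded,
                  spot_umi_min = tot < params$spotUmiMin,
                  spot_gene_min = ng < params$spotGeneMin)
    att <- .attributeDrops(obsIds(m), flags)
    if (!length(att$keep))
        stop("no spots survive QC; review spot thresholds")
    st <- computeObsStats(CountMatrix(cm, "spot"), mitoGenes, character())
    rownames(st) <- obsIds(m)
    obs$total_umi <- st[obs$obs_id, "total_umi"]
    obs$n_genes <- st[obs$obs_id, "n_genes"]
    list(counts = CountMatrix(cm[, att$keep, drop = FALSE], "spot"),
         obs = obs[obs$obs_id %in% att$keep, ],
         report = QCReport(ncol(m), att$dropped, length(att$keep)),
         removedGenes = removedGenes)
}

#' Log-normalize a count matrix
#'
#' Each observation's counts are divided by its total, scaled by S, and
#' transformed with the natural log1p:
#' \code{value(g, o) = ln(1 + count(g, o) / total(o) * S)}. For spots, S is
#' the median of the spot totals (the spatial normalization rule: totals
#' normalized, then scaled by the median transcript count across spots);
#' for cells, S = 10,000, the single-cell ecosystem convention. Zeros map
#' to zero, so sparsity is preserved.
#'
#' @param m A [CountMatrix-class] with no zero-total observations (drop
#'   those in QC first).
#' @param mode \code{"cells"} or \code{"spots"}; picks the scale factor.
#' @return An [ExpressionMatrix-class] recording S and the log base.
#' @export
logNormalize <- function(m, mode = c("cells", "spots")) {
    mode <- match.arg(mode)
    stopifnot(is(m, "CountMatrix"))
    cm <- counts(m)
    tot <- Matrix::colSums(cm)
    if (any(tot == 0))
        stop("zero-total observation(s) reached logNormalize: ",
             paste(head(colnames(cm)[tot == 0], 5), collapse = ", "),
             "; drop them in QC first")
    S <- if (mode == "spots") stats::median(tot) else 1e4
    v <- cm
    # column-wise scaling on the sparse slots only
    v@x <- log1p(cm@x * rep.int(S / tot, diff(cm@p)))
    new("ExpressionMatrix", values = v, scaleFactor = as.numeric(S),
        logBase = exp(1),
        obsKind = if (mode == "cells") "cell" else "spot")
}
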