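#' Simulation configuration for the synthetic thyroid data generator
#'
#' Builds and validates the configuration of the synthetic-data module. The
#' defaults emulate the structure of a postnatal mouse thyroid developmental
#' series: four time points, ten cell types (among them two thyroid
#' follicular cell subtypes, TFC1 and TFC2), mitochondrial / hemoglobin /
#' ribosomal gene classes, a 6\% planted doublet rate, two spatial regions
#' (central and peripheral) whose expression programs share a configurable
#' fraction of genes with their matched cell types, and myeloid-ligand /
#' thyrocyte-receptor channels whose strength decays across the time points.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param timePoints Ordered time point labels.
#' @param nCellsPerTimepoint Cells simulated per time point.
#' @param cellTypeFreqs Named numeric vector of cell-type frequencies
#'   (must sum to 1).
#' @param nGenes Total genes in the matrix (markers, specials and filler).
#' @param nMarkersPerType Planted marker genes per cell type.
#' @param markerLogEffect Log-scale mean shift of a marker in its own type.
#' @param baselineMean Negative-binomial mean of a baseline gene per cell.
#' @param dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi mu^2), shared across genes.
#' @param mitoGeneCount,hbGeneCount,riboGeneCount Number of mitochondrial,
#'   hemoglobin and ribosomal genes.
#' @param mitoFraction,hbFraction Target expected fraction of counts carried
#'   by the mitochondrial and hemoglobin classes.
#' @param doubletRate Fraction of cells per time point planted as doublets
#'   (sums of two parent cells); in [0, 1).
#' @param nSpots Number of spatial spots.
#' @param regionAssignment Named character vector mapping every cell type to
#'   its planted region.
#' @param regionMarkerOverlap Fraction of each type's markers included in
#'   its region's expression program.
#' @param nRegionOnlyGenes Region-program genes not shared with any type.
#' @param regionLogEffect Log-scale elevation of a region-program gene in
#'   its region's spots.
#' @param spotDepthFactor Spot depth relative to a single cell (spots pool
#'   several cells' transcripts).
#' @param lrChannels List of planted ligand-receptor channels; each a list
#'   with \code{pair_id}, \code{ligand}, \code{sender}, \code{receptor},
#'   \code{receiver} and \code{effects} (log-scale, one per time point,
#'   applied to the ligand in the sender and the receptor in the receiver).
#' @param nDecoyPairs Ligand-receptor pairs with no planted effect.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      timePoints = c("d5", "d10", "d20", "d30"),
                      nCellsPerTimepoint = 500L,
                      cellTypeFreqs = c(
                          TFC1 = 0.15, TFC2 = 0.15, Ccell = 0.08,
                          PTC = 0.08, Endo = 0.10, Fibro = 0.12,
                          Myeloid = 0.10, Tcell = 0.08, Bcell = 0.07,
                          Adipo = 0.07),
                      nGenes = 2000L,
                      nMarkersPerType = 20L,
                      markerLogEffect = 2.0,
                      baselineMean = 0.5,
                      dispersion = 0.5,
                      mitoGeneCount = 10L, hbGeneCount = 5L,
                      riboGeneCount = 10L,
                      mitoFraction = 0.04, hbFraction = 0.002,
                      doubletRate = 0.06,
                      nSpots = 454L,
                      regionAssignment = c(
                          TFC1 = "central", Myeloid = "central",
                          Ccell = "central", Endo = "central",
                          Tcell = "central", TFC2 = "peripheral",
                          PTC = "peripheral", Fibro = "peripheral",
                          Bcell = "peripheral", Adipo = "peripheral"),
                      regionMarkerOverlap = 0.6,
                      nRegionOnlyGenes = 10L,
                      regionLogEffect = 1.5,
                      spotDepthFactor = 5,
                      lrChannels = NULL,
                      nDecoyPairs = 5L) {
    if (is.null(lrChannels)) {
        dec <- c(2.0, 1.5, 1.0, 0.5)[seq_along(timePoints)]
        lrChannels <- list(
            list(pair_id = "ch1", ligand = "Lig1", sender = "Myeloid",
                 receptor = "Rec1", receiver = "TFC1", effects = dec),
            list(pair_id = "ch2", ligand = "Lig2", sender = "Myeloid",
                 receptor = "Rec2", receiver = "TFC2", effects = dec),
            list(pair_id = "ch3", ligand = "Lig3", sender = "Fibro",
                 receptor = "Rec3", receiver = "Endo", effects = dec))
    }
    cfg <- list(seed = as.integer(seed), timePoints = timePoints,
                nCellsPerTimepoint = as.integer(nCellsPerTimepoint),
                cellTypeFreqs = cellTypeFreqs, nGenes = as.integer(nGenes),
                nMarkersPerType = as.integer(nMarkersPerType),
                markerLogEffect = markerLogEffect,
                baselineMean = baselineMean, dispersion = dispersion,
                mitoGeneCount = as.integer(mitoGeneCount),
                hbGeneCount = as.integer(hbGeneCount),
                riboGeneCount = as.integer(riboGeneCount),
                mitoFraction = mitoFraction, hbFraction = hbFraction,
                doubletRate = doubletRate, nSpots = as.integer(nSpots),
                regionAssignment = regionAssignment,
                regionMarkerOverlap = regionMarkerOverlap,
                nRegionOnlyGenes = as.integer(nRegionOnlyGenes),
                regionLogEffect = regionLogEffect,
                spotDepthFactor = spotDepthFactor,
                lrChannels = lrChannels,
                nDecoyPairs = as.integer(nDecoyPairs))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' Validate a SimConfig
#'
#' @param cfg A \code{SimConfig} list.
#' @return \code{cfg}, invisibly, or an error.
#' @export
validateSimConfig <- function(cfg) {
    if (abs(sum(cfg$cellTypeFreqs) - 1) > 1e-8)
        stop("cell type frequencies must sum to 1")
    if (cfg$doubletRate < 0 || cfg$doubletRate >= 1)
        stop("doubletRate must lie in [0, 1)")
    if (any(c(cfg$nCellsPerTimepoint, cfg$nGenes, cfg$nMarkersPerType,
              cfg$nSpots) <= 0))
        stop("all counts must be positive")
    layout <- .simGeneLayout(cfg)  # errors if nGenes too small
    types <- names(cfg$cellTypeFreqs)
    if (!setequal(names(cfg$regionAssignment), types))
        stop("regionAssignment must cover exactly the configured cell types")
    if (!length(unique(cfg$regionAssignment)))
        stop("regions must be non-empty")
    for (ch in cfg$lrChannels) {
        if (!ch$sender %in% types || !ch$receiver %in% types)
            stop("ligand-receptor channel '", ch$pair_id,
                 "': sender/receiver not in cell types")
        if (length(ch$effects) != length(cfg$timePoints))
            stop("channel '", ch$pair_id,
                 "' must give one effect per time point")
    }
    invisible(cfg)
}

# Deterministic child seed per simulation stage, kept below 2^31.
.childSeed <- function(seed, offset) {
    (as.numeric(seed) * 48271 + offset * 10007) %% 2147483647
}

# Assign every gene a role and a name. Markers belong to exactly one type;
# region programs reuse a fixed leading fraction of the matched types'
# markers plus region-only genes.
.simGeneLayout <- function(cfg) {
    types <- names(cfg$cellTypeFreqs)
    regions <- unique(unname(cfg$regionAssignment))
    markers <- lapply(types, function(t)
        sprintf("Mk%s_%02d", t, seq_len(cfg$nMarkersPerType)))
    names(markers) <- types
    regionOnly <- lapply(regions, function(r)
        sprintf("Reg%s_%02d", r, seq_len(cfg$nRegionOnlyGenes)))
    names(regionOnly) <- regions
    mito <- sprintf("mt-%02d", seq_len(cfg$mitoGeneCount))
    hb <- sprintf("Hb_%02d", seq_len(cfg$hbGeneCount))
    ribo <- sprintf("Rps_%02d", seq_len(cfg$riboGeneCount))
    lig <- vapply(cfg$lrChannels, `[[`, "", "ligand")
    rec <- vapply(cfg$lrChannels, `[[`, "", "receptor")
    decoyLig <- sprintf("LigD%d", seq_len(cfg$nDecoyPairs))
    decoyRec <- sprintf("RecD%d", seq_len(cfg$nDecoyPairs))
    special <- c(unlist(markers), unlist(regionOnly), mito, hb, ribo,
                 lig, rec, decoyLig, decoyRec)
    if (anyDuplicated(special))
        stop("internal: duplicated planted gene names")
    nFiller <- cfg$nGenes - length(special)
    if (nFiller < 0)
        stop("nGenes (", cfg$nGenes, ") too small for ",
             length(special), " planted genes ",
             "(markers per type x types plus special classes)")
    filler <- sprintf("Gene%04d", seq_len(nFiller))
    nShared <- round(cfg$regionMarkerOverlap * cfg$nMarkersPerType)
    regionProgram <- lapply(regions, function(r) {
        shared <- unlist(lapply(types[cfg$regionAssignment[types] == r],
                                function(t) markers[[t]][seq_len(nShared)]))
        c(shared, regionOnly[[r]])
    })
    names(regionProgram) <- regions
    list(genes = c(special, filler), markers = markers,
         regionOnly = regionOnly, regionProgram = regionProgram,
         mito = mito, hb = hb, ribo = ribo,
         ligands = lig, receptors = rec,
         decoyLigands = decoyLig, decoyReceptors = decoyRec)
}

# Baseline per-gene NB means shared by both modalities (single-cell depth).
.simBaseMeans <- function(cfg, layout) {
    mu <- rep(cfg$baselineMean, cfg$nGenes)
    names(mu) <- layout$genes
    # expected per-cell total from non-mito/hb genes, including the average
    # marker boost, so the mito/hb classes land near their target fractions
    boost <- cfg$nMarkersPerType * cfg$baselineMean *
        (exp(cfg$markerLogEffect) - 1)
    eTot <- cfg$baselineMean *
        (cfg$nGenes - cfg$mitoGeneCount - cfg$hbGeneCount) + boost
    mu[layout$mito] <- cfg$mitoFraction * eTot /
        ((1 - cfg$mitoFraction - cfg$hbFraction) * cfg$mitoGeneCount)
    mu[layout$hb] <- cfg$hbFraction * eTot /
        ((1 - cfg$mitoFraction - cfg$hbFraction) * cfg$hbGeneCount)
    mu[layout$ribo] <- 2 * cfg$baselineMean
    mu
}

#' Generate a synthetic scRNA-seq data set with planted truth
#'
#' Draws negative-binomial UMI counts for \code{nCellsPerTimepoint} cells at
#' each time point. A gene's mean in a cell of type t is
#' \code{mu_g * exp(effect_{g,t})}: markers of t carry
#' \code{markerLogEffect}; planted ligand (sender) and receptor (receiver)
#' genes carry their channel's per-time-point effect. A
#' \code{doubletRate} fraction of cells per time point (rounded to the
#' nearest integer, planted not sampled) are sums of two independently drawn
#' parent cells and flagged in the truth; planted doublets get
#' \code{doublet_score = 1}, singlets uniform noise in [0, 0.5). Fully
#' deterministic given \code{cfg$seed}.
#'
#' @param cfg A [simConfig()] object.
#' @return A list with elements \code{counts} ([CountMatrix-class]),
#'   \code{obs} (observation DataFrame) and \code{truth}
#'   ([SyntheticTruth-class]).
#' @export
generateScrna <- function(cfg) {
    validateSimConfig(cfg)
    layout <- .simGeneLayout(cfg)
    baseMu <- .simBaseMeans(cfg, layout)
    types <- names(cfg$cellTypeFreqs)
    size <- 1 / cfg$dispersion

    # per-type mean matrix at a given time point index
    typeMu <- function(t, ti) {
        mu <- baseMu
        mu[layout$markers[[t]]] <- mu[layout$markers[[t]]] *
            exp(cfg$markerLogEffect)
        for (ch in cfg$lrChannels) {
            if (ch$sender == t)
                mu[ch$ligand] <- mu[ch$ligand] * exp(ch$effects[ti])
            if (ch$receiver == t)
                mu[ch$receptor] <- mu[ch$receptor] * exp(ch$effects[ti])
        }
        mu
    }

    set.seed(.childSeed(cfg$seed, 1L))
    blocks <- list(); obsL <- list(); truthObsL <- list()
    n <- cfg$nCellsPerTimepoint
    for (ti in seq_along(cfg$timePoints)) {
        tp <- cfg$timePoints[ti]
        cellType <- sample(types, n, replace = TRUE,
                           prob = cfg$cellTypeFreqs)
        nd <- round(cfg$doubletRate * n)
        dbl <- sort(sample.int(n, nd))
        parent2 <- rep(NA_character_, n)
        parent2[dbl] <- sample(types, nd, replace = TRUE,
                               prob = cfg$cellTypeFreqs)
        muMat <- vapply(cellType, typeMu, numeric(cfg$nGenes), ti = ti)
        cnt <- matrix(stats::rnbinom(length(muMat), mu = muMat, size = size),
                      nrow = cfg$nGenes)
        if (nd) {
            mu2 <- vapply(parent2[dbl], typeMu, numeric(cfg$nGenes), ti = ti)
            cnt[, dbl] <- cnt[, dbl, drop = FALSE] +
                matrix(stats::rnbinom(length(mu2), mu = mu2, size = size),
                       nrow = cfg$nGenes)
        }
        score <- stats::runif(n, 0, 0.5)
        score[dbl] <- 1
        barcode <- sprintf("c%s-%04d", tp, seq_len(n))
        dimnames(cnt) <- list(layout$genes, barcode)
        blocks[[ti]] <- Matrix::Matrix(cnt, sparse = TRUE)
        obsL[[ti]] <- data.frame(
            obs_id = barcode, group_label = cellType, time_point = tp,
            doublet_score = score, stringsAsFactors = FALSE)
        truthObsL[[ti]] <- data.frame(
            obs_id = barcode, true_type = cellType, time_point = tp,
            is_doublet = seq_len(n) %in% dbl, parent2 = parent2,
            stringsAsFactors = FALSE)
    }
    m <- CountMatrix(do.call(cbind, blocks), "cell")
    obs <- do.call(rbind, obsL)
    obs <- cbind(obs, computeObsStats(m, layout$mito, layout$hb))
    obs <- validateObsTable(obs, "cell", obsIds(m))
    truth <- .buildTruth(cfg, layout, scObs = do.call(rbind, truthObsL))
    list(counts = m, obs = obs, truth = truth)
}

#' Generate a synthetic spatial-transcriptomics section with planted truth
#'
#' Lays \code{nSpots} spots on a square grid, labels the spots nearest the
#' grid centre as the central region and the rest as peripheral, and draws
#' negative-binomial counts in which each region's program genes (a fixed
#' fraction of the matched cell types' markers plus region-only genes) are
#' elevated by \code{exp(regionLogEffect)} in that region's spots. The gene
#' universe is identical to the scRNA-seq one. Deterministic given the seed.
#'
#' @param cfg A [simConfig()] object.
#' @return A list with \code{counts}, \code{obs}, \code{truth} as in
#'   [generateScrna()].
#' @export
generateSt <- function(cfg) {
    validateSimConfig(cfg)
    layout <- .simGeneLayout(cfg)
    regions <- unique(unname(cfg$regionAssignment))
    if (!length(regions)) stop("regions must be non-empty")
    baseMu <- .simBaseMeans(cfg, layout) * cfg$spotDepthFactor
    size <- 1 / cfg$dispersion

    nx <- ceiling(sqrt(cfg$nSpots))
    xy <- expand.grid(x = seq_len(nx), y = seq_len(nx))[seq_len(cfg$nSpots), ]
    d <- sqrt((xy$x - mean(range(xy$x)))^2 + (xy$y - mean(range(xy$y)))^2)
    central <- rank(d, ties.method = "first") <= floor(cfg$nSpots / 2)
    region <- ifelse(central, regions[1], regions[2])

    regionMu <- function(r) {
        mu <- baseMu
        prog <- layout$regionProgram[[r]]
        mu[prog] <- mu[prog] * exp(cfg$regionLogEffect)
        mu
    }
    set.seed(.childSeed(cfg$seed, 2L))
    muMat <- vapply(region, regionMu, numeric(cfg$nGenes))
    cnt <- matrix(stats::rnbinom(length(muMat), mu = muMat, size = size),
                  nrow = cfg$nGenes)
    barcode <- sprintf("s%04d", seq_len(cfg$nSpots))
    dimnames(cnt) <- list(layout$genes, barcode)
    m <- CountMatrix(Matrix::Matrix(cnt, sparse = TRUE), "spot")
    obs <- data.frame(
        obs_id = barcode, group_label = region, time_point = "d10",
        x = xy$x, y = xy$y, stringsAsFactors = FALSE)
    obs <- cbind(obs, computeObsStats(m, layout$mito, layout$hb))
    obs <- validateObsTable(obs, "spot", obsIds(m))
    truth <- .buildTruth(cfg, layout,
                         stObs = data.frame(obs_id = barcode,
                                            true_region = region,
                                            x = xy$x, y = xy$y,
                                            stringsAsFactors = FALSE))
    list(counts = m, obs = obs, truth = truth)
}

#' Ligand-receptor database implied by a simulation configuration
#'
#' Returns the planted channels plus the configured number of decoy pairs
#' (genes present in the matrix with no planted effect at any time point).
#'
#' @param cfg A [simConfig()] object.
#' @return An [LRDatabase-class].
#' @export
generateLRDatabase <- function(cfg) {
    validateSimConfig(cfg)
    layout <- .simGeneLayout(cfg)
    planted <- data.frame(
        pair_id = vapply(cfg$lrChannels, `[[`, "", "pair_id"),
        ligand = layout$ligands, receptor = layout$receptors,
        source_annotation = "planted", stringsAsFactors = FALSE)
    decoy <- data.frame(
        pair_id = sprintf("decoy%d", seq_len(cfg$nDecoyPairs)),
        ligand = layout$decoyLigands, receptor = layout$decoyReceptors,
        source_annotation = "decoy", stringsAsFactors = FALSE)
    LRDatabase(rbind(planted, decoy))
}

#' SyntheticTruth: planted ground truth of a simulated data set
#'
#' @slot genes Per-gene roles: columns \code{gene}, \code{role}
#'   (baseline / marker / region-only / mito / hb / ribo / ligand /
#'   receptor), \code{type} (marker owner or channel type, else NA) and
#'   \code{region} (region program membership, else NA).
#' @slot obs Per-observation truth: true type / region, doublet flags.
#' @slot typeRegion Planted cell-type to region correspondence.
#' @slot channels Planted ligand-receptor channels with their per-time-point
#'   effect schedule (decoys listed with all-zero effects).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(genes = "data.frame", obs = "data.frame",
                   typeRegion = "data.frame", channels = "data.frame"))

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(paste0("SyntheticTruth: %d genes, %d observations, ",
                       "%d type-region links, %d channels\n"),
                nrow(object@genes), nrow(object@obs),
                nrow(object@typeRegion), nrow(object@channels)))
})

.buildTruth <- function(cfg, layout, scObs = NULL, stObs = NULL) {
    types <- names(cfg$cellTypeFreqs)
    genes <- data.frame(gene = layout$genes, role = "baseline",
                        type = NA_character_, region = NA_character_,
                        stringsAsFactors = FALSE)
    rownames(genes) <- genes$gene
    for (t in types) {
        genes[layout$markers[[t]], "role"] <- "marker"
        genes[layout$markers[[t]], "type"] <- t
    }
    for (r in names(layout$regionOnly))
        genes[layout$regionOnly[[r]], "role"] <- "region-only"
    for (r in names(layout$regionProgram))
        genes[layout$regionProgram[[r]], "region"] <- r
    genes[layout$mito, "role"] <- "mito"
    genes[layout$hb, "role"] <- "hb"
    genes[layout$ribo, "role"] <- "ribo"
    chan <- do.call(rbind, lapply(cfg$lrChannels, function(ch) {
        genes[ch$ligand, c("role", "type")] <<- c("ligand", ch$sender)
        genes[ch$receptor, c("role", "type")] <<- c("receptor", ch$receiver)
        eff <- as.data.frame(as.list(stats::setNames(
            ch$effects, paste0("effect_", cfg$timePoints))))
        cbind(data.frame(pair_id = ch$pair_id, ligand = ch$ligand,
                         sender = ch$sender, receptor = ch$receptor,
                         receiver = ch$receiver,
                         stringsAsFactors = FALSE), eff)
    }))
    genes[layout$decoyLigands, "role"] <- "ligand"
    genes[layout$decoyReceptors, "role"] <- "receptor"
    if (cfg$nDecoyPairs > 0) {
        zeros <- as.data.frame(as.list(stats::setNames(
            rep(0, length(cfg$timePoints)),
            paste0("effect_", cfg$timePoints))))
        decoys <- cbind(data.frame(
            pair_id = sprintf("decoy%d", seq_len(cfg$nDecoyPairs)),
            ligand = layout$decoyLigands, sender = NA_character_,
            receptor = layout$decoyReceptors, receiver = NA_character_,
            stringsAsFactors = FALSE),
            zeros[rep(1, cfg$nDecoyPairs), , drop = FALSE])
        chan <- rbind(chan, decoys)
    }
    rownames(genes) <- NULL
    rownames(chan) <- NULL
    obs <- if (!is.null(scObs)) scObs else stObs
    new("SyntheticTruth", genes = genes, obs = obs,
        typeRegion = data.frame(type = types,
                                region = unname(cfg$regionAssignment[types]),
                                stringsAsFactors = FALSE),
        channels = chan)
}

#' Write / read a SyntheticTruth as TSV files
#'
#' Four TSVs (\code{truth_genes.tsv}, \code{truth_obs.tsv},
#' \code{truth_type_region.tsv}, \code{truth_channels.tsv}) under
#' \code{dir}; the round trip reproduces the object.
#'
#' @param truth A [SyntheticTruth-class].
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
writeSyntheticTruth <- function(truth, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("truth_genes.tsv", "truth_obs.tsv",
                              "truth_type_region.tsv",
                              "truth_channels.tsv"))
    writeResultTSV(truth@genes, paths[1])
    writeResultTSV(truth@obs, paths[2])
    writeResultTSV(truth@typeRegion, paths[3])
    writeResultTSV(truth@channels, paths[4])
    invisible(paths)
}

#' @rdname writeSyntheticTruth
#' @export
readSyntheticTruth <- function(dir) {
    rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                        quote = "", stringsAsFactors = FALSE)
    new("SyntheticTruth", genes = rd("truth_genes.tsv"),
        obs = rd("truth_obs.tsv"),
        typeRegion = rd("truth_type_region.tsv"),
        channels = rd("truth_channels.tsv"))
}

#' Gene class lists of a simulated data set
#'
#' Convenience accessor for the mitochondrial, hemoglobin and ribosomal gene
#' names implied by a configuration (the classes QC filters need).
#'
#' @param cfg A [simConfig()] object.
#' @return A list with elements \code{mito}, \code{hb}, \code{ribo},
#'   \code{markers} (named list per type) and \code{regionProgram}.
#' @export
simGeneClasses <- function(cfg) {
    layout <- .simGeneLayout(cfg)
    list(mito = layout$mito, hb = layout$hb, ribo = layout$ribo,
         markers = layout$markers, regionProgram = layout$regionProgram)
}
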