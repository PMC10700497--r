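#' Pipeline run configuration
#'
#' Bundles every stage's parameters into one validated object. Each
#' modality comes either from the synthetic generator (a [simConfig()]
#' block) or from files on disk — exactly one of the two.
#'
#' @param seed Global seed; per-stage streams are derived from it
#'   deterministically, so stages can be re-run in isolation.
#' @param sim A [simConfig()] used for both modalities when simulating
#'   (its seed is overridden by \code{seed}).
#' @param scrnaPaths,stPaths Optional named lists
#'   (\code{mtx}, \code{genes}, \code{barcodes}, \code{obs}) of input
#'   files; supplying one disables simulation for that modality.
#' @param lrPath,orthologPath Optional ligand-receptor CSV and ortholog
#'   TSV; when absent and simulating, the database implied by \code{sim}
#'   is used.
#' @param qc A [qcParams()] object.
#' @param markerTest \code{"ttest"} or \code{"wilcoxon"} for the cell-type
#'   sets (the region sets always use the t test at \code{stPThreshold}).
#' @param scPThreshold,stPThreshold Strict p thresholds for the cell-type
#'   (default 1e-20) and region (default 1e-3) gene sets.
#' @param adjust Threshold BH-adjusted p values when building sets.
#' @param logfcMin Optional minimum average log fold change for set
#'   membership.
#' @param miaBackgroundMode Background rule for [miaMap()].
#' @param perm A [permConfig()] (its seed is overridden by \code{seed}).
#' @param sigThreshold Significance threshold for interaction counting.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, sim = simConfig(),
                           scrnaPaths = NULL, stPaths = NULL,
                           simulateScrna = NULL, simulateSt = NULL,
                           lrPath = NULL, orthologPath = NULL,
                           qc = qcParams(), markerTest = "ttest",
                           scPThreshold = 1e-20, stPThreshold = 1e-3,
                           adjust = FALSE, logfcMin = NULL,
                           miaBackgroundMode = "intersection",
                           perm = permConfig(), sigThreshold = 0.05) {
    if (is.null(simulateScrna)) simulateScrna <- is.null(scrnaPaths)
    if (is.null(simulateSt)) simulateSt <- is.null(stPaths)
    if (simulateScrna && !is.null(scrnaPaths))
        stop("scRNA modality: give either input paths or a simulate ",
             "block, not both")
    if (simulateSt && !is.null(stPaths))
        stop("ST modality: give either input paths or a simulate block, ",
             "not both")
    if (!simulateScrna && is.null(scrnaPaths))
        stop("scRNA modality: either input paths or simulation required")
    if (!simulateSt && is.null(stPaths))
        stop("ST modality: either input paths or simulation required")
    for (pp in list(scrnaPaths, stPaths)) {
        if (is.null(pp)) next
        need <- c("mtx", "genes", "barcodes", "obs")
        if (!all(need %in% names(pp)))
            stop("input path lists need elements: ",
                 paste(need, collapse = ", "))
        missing <- !vapply(unlist(pp[need]), file.exists, TRUE)
        if (any(missing))
            stop("input file(s) not found: ",
                 paste(unlist(pp[need])[missing], collapse = ", "))
    }
    cfg <- list(seed = as.integer(seed), sim = sim,
                simulateScrna = simulateScrna, simulateSt = simulateSt,
                scrnaPaths = scrnaPaths, stPaths = stPaths,
                lrPath = lrPath, orthologPath = orthologPath, qc = qc,
                markerTest = markerTest, scPThreshold = scPThreshold,
                stPThreshold = stPThreshold, adjust = adjust,
                logfcMin = logfcMin,
                miaBackgroundMode = miaBackgroundMode, perm = perm,
                sigThreshold = sigThreshold)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Small self-contained demonstration configuration
#'
#' A scaled-down simulate-only run (120 cells per time point, 600 genes,
#' 10 markers per type, 100 spots, 200 permutations) that exercises every
#' stage in well under five minutes on one CPU.
#'
#' @param seed Global seed.
#' @return A [pipelineConfig()].
#' @export
demoPipelineConfig <- function(seed = 1L) {
    pipelineConfig(
        seed = seed,
        sim = simConfig(seed = seed, nCellsPerTimepoint = 120L,
                        nGenes = 600L, nMarkersPerType = 10L,
                        nSpots = 100L),
        # at demo depth the smallest types have ~30 cells; the marker-set
        # threshold scales with that power
        scPThreshold = 1e-10,
        perm = permConfig(nPermutations = 200L, seed = seed))
}

.qcReportDF <- function(report, stage) {
    data.frame(stage = stage,
               rule = c("n_in", names(report@nDropped), "n_out"),
               count = c(report@nIn, unname(report@nDropped), report@nOut),
               stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or read) -> cell/gene/doublet QC -> spot QC ->
#' log-normalization -> marker gene sets -> MIA map -> ligand-receptor
#' interactions, writing every stage's output under \code{outDir} in the
#' same formats the package's readers accept, plus a machine-readable run
#' manifest (\code{manifest.json}) with the configuration hash, per-stage
#' record counts and per-file checksums. Outputs carry no timestamps, so
#' re-running an identical configuration reproduces identical checksums;
#' the manifest's own timestamp is the only volatile field.
#'
#' @param cfg A [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param quiet Suppress stage-tagged progress lines on stderr.
#' @return Invisibly, a list with all stage objects and the manifest.
#' @export
runPipeline <- function(cfg, outDir, quiet = FALSE) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    say <- function(stage, ...) if (!quiet)
        message(sprintf("[%s] ", stage), ...)
    stages <- list()

    ## ---- scRNA input ----
    simCfg <- cfg$sim; simCfg$seed <- cfg$seed
    classes <- simGeneClasses(simCfg)
    if (cfg$simulateScrna) {
        say("simulate", "generating scRNA counts")
        sc <- generateScrna(simCfg)
        writeSyntheticTruth(sc$truth, file.path(outDir, "truth_scrna"))
    } else {
        sc <- list(counts = readCountMatrix(cfg$scrnaPaths$mtx,
                                            cfg$scrnaPaths$genes,
                                            cfg$scrnaPaths$barcodes, "cell"),
                   obs = readObsTable(cfg$scrnaPaths$obs, "cell"),
                   truth = NULL)
        # gene classes by symbol convention when reading external data
        g <- geneIds(sc$counts)
        classes <- list(mito = grep("^mt-", g, value = TRUE,
                                    ignore.case = TRUE),
                        hb = grep("^Hb", g, value = TRUE),
                        ribo = grep("^Rp[sl]", g, value = TRUE,
                                    ignore.case = TRUE))
    }
    writeCountMatrix(sc$counts, file.path(outDir, "scrna_raw"))
    writeObsTable(sc$obs, file.path(outDir, "scrna_raw.obs.tsv"))
    stages$scrna_raw <- ncol(sc$counts)

    ## ---- cell QC ----
    say("qc", "filtering cells, genes and doublets")
    qcC <- qcCells(sc$counts, sc$obs, cfg$qc, classes$mito, classes$hb)
    qcG <- qcGenes(qcC$counts, cfg$qc)
    qcD <- qcDoublets(qcC$obs, cfg$qc)
    keep <- intersect(obsIds(qcG$counts), qcD$kept)
    cells <- CountMatrix(counts(qcG$counts)[, keep, drop = FALSE], "cell")
    cellObs <- qcC$obs[match(keep, qcC$obs$obs_id), ]
    stages$cells_post_qc <- ncol(cells)
    stages$genes_post_qc <- nrow(cells)
    qcdf <- rbind(.qcReportDF(qcC$report, "cells"),
                  .qcReportDF(qcG$report, "genes"),
                  .qcReportDF(qcD$report, "doublets"))

    ## ---- ST input + QC ----
    if (cfg$simulateSt) {
        say("simulate", "generating spatial counts")
        st <- generateSt(simCfg)
        writeSyntheticTruth(st$truth, file.path(outDir, "truth_st"))
    } else {
        st <- list(counts = readCountMatrix(cfg$stPaths$mtx,
                                            cfg$stPaths$genes,
                                            cfg$stPaths$barcodes, "spot"),
                   obs = readObsTable(cfg$stPaths$obs, "spot"),
                   truth = NULL)
    }
    writeCountMatrix(st$counts, file.path(outDir, "st_raw"))
    stages$spots_raw <- ncol(st$counts)
    qcS <- qcSpots(st$counts, st$obs, cfg$qc, classes$mito, classes$ribo)
    spots <- qcS$counts
    spotObs <- qcS$obs[match(obsIds(spots), qcS$obs$obs_id), ]
    stages$spots_post_qc <- ncol(spots)
    qcdf <- rbind(qcdf, .qcReportDF(qcS$report, "spots"))
    writeResultTSV(qcdf, file.path(outDir, "qc_report.tsv"))

    ## ---- normalization ----
    say("normalize", "log-normalizing both modalities")
    exprC <- logNormalize(cells, "cells")
    exprS <- logNormalize(spots, "spots")

    ## ---- marker sets ----
    say("markers", "building cell-type and region gene sets")
    typeSets <- buildGeneSets(exprC, cellObs$group_label,
                              test = cfg$markerTest,
                              pThreshold = cfg$scPThreshold,
                              adjust = cfg$adjust, logfcMin = cfg$logfcMin,
                              modality = "scRNA")
    regionSets <- buildGeneSets(exprS, spotObs$group_label, test = "ttest",
                                pThreshold = cfg$stPThreshold,
                                adjust = cfg$adjust, modality = "ST")
    writeGMT(typeSets, file.path(outDir, "type_sets.gmt"))
    writeGMT(regionSets, file.path(outDir, "region_sets.gmt"))
    stages$type_sets <- length(typeSets)
    stages$region_sets <- length(regionSets)

    ## ---- MIA ----
    say("mia", "computing the MIA map")
    mia <- miaMap(typeSets, regionSets, universeA = geneIds(exprC),
                  universeB = geneIds(exprS),
                  backgroundMode = cfg$miaBackgroundMode)
    writeMIAMap(mia, file.path(outDir, "mia.tsv"))
    stages$mia_pairs <- nrow(miaTable(mia))

    ## ---- ligand-receptor interactions ----
    say("interactions", "scoring ligand-receptor interactions")
    ortho <- if (!is.null(cfg$orthologPath))
        readOrthologMap(cfg$orthologPath) else NULL
    lrdb <- if (!is.null(cfg$lrPath)) readLRDatabase(cfg$lrPath, ortho)
            else generateLRDatabase(simCfg)
    permCfg <- cfg$perm
    permCfg$seed <- as.integer(.childSeed(cfg$seed, 3L))
    it <- interactionTable(exprC, cellObs$group_label, cellObs$time_point,
                           lrdb, permCfg)
    writeInteractionTable(it, file.path(outDir, "interactions.tsv"),
                          file.path(outDir, "interaction_counts.tsv"),
                          cfg$sigThreshold)
    stages$interaction_records <- nrow(interactions(it))

    ## ---- manifest ----
    manifest <- .writeManifest(cfg, outDir, stages)
    say("done", "manifest written to ", file.path(outDir, "manifest.json"))
    invisible(list(cells = cells, cellObs = cellObs, spots = spots,
                   spotObs = spotObs, exprCells = exprC, exprSpots = exprS,
                   typeSets = typeSets, regionSets = regionSets, mia = mia,
                   interactions = it, lrdb = lrdb,
                   scTruth = sc$truth, stTruth = st$truth,
                   manifest = manifest))
}

.configHash <- function(cfg) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(unclass(rapply(cfg, unclass, how = "replace")),
                                auto_unbox = TRUE, digits = NA,
                                force = TRUE, null = "null"), tmp)
    unname(tools::md5sum(tmp))
}

.writeManifest <- function(cfg, outDir, stages) {
    files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                          "manifest.json"))
    sums <- tools::md5sum(file.path(outDir, files))
    manifest <- list(
        package = "follimap",
        version = as.character(utils::packageVersion("follimap")),
        seed = cfg$seed,
        config_hash = .configHash(cfg),
        stages = stages,
        files = as.list(stats::setNames(unname(sums), files)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys: \code{seed}, \code{sim} (arguments of
#' [simConfig()]), \code{qc} (arguments of [qcParams()]), \code{perm}
#' (arguments of [permConfig()]), \code{scrna_paths}, \code{st_paths},
#' \code{lr_path}, \code{ortholog_path}, \code{marker_test},
#' \code{sc_p_threshold}, \code{st_p_threshold}, \code{adjust},
#' \code{logfc_min}, \code{mia_background_mode}, \code{sig_threshold}.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
    raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
           else yaml::read_yaml(path)
    simArgs <- raw$sim
    if (!is.null(simArgs$cellTypeFreqs))
        simArgs$cellTypeFreqs <- unlist(simArgs$cellTypeFreqs)
    if (!is.null(simArgs$regionAssignment))
        simArgs$regionAssignment <- unlist(simArgs$regionAssignment)
    pick <- function(key, default) if (is.null(raw[[key]])) default
                                   else raw[[key]]
    pipelineConfig(
        seed = pick("seed", 1L),
        sim = do.call(simConfig, if (is.null(simArgs)) list() else simArgs),
        scrnaPaths = raw$scrna_paths, stPaths = raw$st_paths,
        lrPath = raw$lr_path, orthologPath = raw$ortholog_path,
        qc = do.call(qcParams, if (is.null(raw$qc)) list() else raw$qc),
        markerTest = pick("marker_test", "ttest"),
        scPThreshold = pick("sc_p_threshold", 1e-20),
        stPThreshold = pick("st_p_threshold", 1e-3),
        adjust = pick("adjust", FALSE),
        logfcMin = raw$logfc_min,
        miaBackgroundMode = pick("mia_background_mode", "intersection"),
        perm = do.call(permConfig, if (is.null(raw$perm)) list()
                       else raw$perm),
        sigThreshold = pick("sig_threshold", 0.05))
}
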