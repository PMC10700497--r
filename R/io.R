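#' Read a sparse count matrix from MatrixMarket + sidecar files
#'
#' Reads the 10x-style triple: a MatrixMarket coordinate file of integer
#' counts plus one-identifier-per-line gene and barcode sidecars. Indices in
#' the file are 1-based per the MatrixMarket standard; in-memory objects are
#' addressed by name.
#'
#' @param mtxPath Path to the .mtx coordinate file (genes x observations).
#' @param genesPath Path to the gene sidecar, one symbol per line.
#' @param barcodesPath Path to the barcode sidecar, one barcode per line.
#' @param obsKind \code{"cell"} or \code{"spot"}.
#' @return A [CountMatrix-class].
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(mtxPath, genesPath, barcodesPath,
                            obsKind = c("cell", "spot")) {
    obsKind <- match.arg(obsKind)
    for (p in c(mtxPath, genesPath, barcodesPath))
        if (!file.exists(p)) stop("file not found: ", p)
    m <- Matrix::readMM(mtxPath)
    if (length(m@x) && any(m@x != round(m@x)))
        stop("non-integer values in ", mtxPath)
    if (length(m@x) && any(m@x < 0))
        stop("negative counts in ", mtxPath)
    genes <- readLines(genesPath)
    barcodes <- readLines(barcodesPath)
    if (length(genes) != nrow(m))
        stop("dimension mismatch: ", mtxPath, " declares ", nrow(m),
             " rows but ", genesPath, " has ", length(genes), " genes")
    if (length(barcodes) != ncol(m))
        stop("dimension mismatch: ", mtxPath, " declares ", ncol(m),
             " columns but ", barcodesPath, " has ", length(barcodes),
             " barcodes")
    if (anyDuplicated(genes))
        stop("duplicate gene identifiers in ", genesPath)
    if (anyDuplicated(barcodes))
        stop("duplicate barcodes in ", barcodesPath)
    dimnames(m) <- list(genes, barcodes)
    CountMatrix(m, obsKind)
}

#' Write a CountMatrix as MatrixMarket + sidecars
#'
#' Writes \code{<prefix>.mtx}, \code{<prefix>.genes.tsv} and
#' \code{<prefix>.barcodes.tsv}. Entries are written in a deterministic
#' order (row-major: by gene index, then observation index) so repeated
#' writes of the same matrix are byte-identical.
#'
#' @param m A [CountMatrix-class].
#' @param outPrefix Path prefix for the three output files.
#' @return Invisibly, the three file paths.
#' @export
writeCountMatrix <- function(m, outPrefix) {
    stopifnot(is(m, "CountMatrix"))
    dir.create(dirname(outPrefix), recursive = TRUE, showWarnings = FALSE)
    paths <- paste0(outPrefix, c(".mtx", ".genes.tsv", ".barcodes.tsv"))
    tm <- as(m@counts, "TsparseMatrix")
    i <- tm@i + 1L; j <- tm@j + 1L; x <- as.integer(tm@x)
    o <- order(i, j)
    con <- file(paths[1], "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 paste(nrow(tm), ncol(tm), length(x))), con)
    if (length(x))
        writeLines(paste(i[o], j[o], x[o]), con)
    writeLines(rownames(tm), paths[2])
    writeLines(colnames(tm), paths[3])
    invisible(paths)
}

.OBS_OPTIONAL <- c("group_label", "time_point", "total_umi", "n_genes",
                   "mito_fraction", "hb_fraction", "doublet_score")

#' Validate an observation table
#'
#' Checks the per-observation metadata table: \code{obs_id} present and
#' unique, spot tables carry \code{x} and \code{y} coordinates, and
#' mitochondrial / hemoglobin fractions lie in [0, 1].
#'
#' @param tbl A data.frame or DataFrame of per-observation metadata.
#' @param obsKind \code{"cell"} or \code{"spot"}.
#' @param obsIds Optional: the barcodes of the CountMatrix the table must
#'   annotate; the obs_id sets must then be equal.
#' @return The table as an [S4Vectors::DataFrame], invisibly validated.
#' @export
validateObsTable <- function(tbl, obsKind = c("cell", "spot"),
                             obsIds = NULL) {
    obsKind <- match.arg(obsKind)
    tbl <- S4Vectors::DataFrame(tbl, check.names = FALSE)
    required <- "obs_id"
    if (obsKind == "spot") required <- c(required, "x", "y")
    missing_req <- setdiff(required, colnames(tbl))
    if (length(missing_req))
        stop("observation table is missing required column(s) for obs_kind='",
             obsKind, "': ", paste(missing_req, collapse = ", "))
    if (anyDuplicated(tbl$obs_id))
        stop("duplicate obs_id in observation table")
    for (col in c("mito_fraction", "hb_fraction")) {
        v <- tbl[[col]]
        if (!is.null(v) && any(!is.na(v) & (v < 0 | v > 1)))
            stop(col, " must lie in [0, 1]")
    }
    if (!is.null(obsIds) && !setequal(tbl$obs_id, obsIds))
        stop("observation table obs_ids do not match the count matrix")
    S4Vectors::metadata(tbl)$obs_kind <- obsKind
    S4Vectors::metadata(tbl)$missing_optional <-
        setdiff(.OBS_OPTIONAL, colnames(tbl))
    tbl
}

#' Read an observation (cell/spot metadata) table
#'
#' Tab-separated, UTF-8, mandatory header, no quoting. Missing optional
#' columns are allowed; their names are recorded in
#' \code{metadata(tbl)$missing_optional}.
#'
#' @inheritParams validateObsTable
#' @param path Path to the TSV file.
#' @return A validated [S4Vectors::DataFrame].
#' @export
readObsTable <- function(path, obsKind = c("cell", "spot")) {
    obsKind <- match.arg(obsKind)
    tbl <- utils::read.delim(path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, check.names = FALSE)
    validateObsTable(tbl, obsKind)
}

#' Write an observation table as TSV
#'
#' @param tbl A data.frame or DataFrame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeObsTable <- function(tbl, path) {
    writeResultTSV(as.data.frame(tbl), path)
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, no quoting, no row names: the dialect every
#' follimap artifact uses, so outputs are byte-stable across runs.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeResultTSV <- function(df, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read an ortholog map
#'
#' TSV with columns \code{source} and \code{target} (e.g. human symbol to
#' mouse symbol). The map is the only renaming mechanism in the package;
#' matching is case-sensitive.
#'
#' @param path Path to the TSV file.
#' @return A named character vector: \code{target[source]}.
#' @export
readOrthologMap <- function(path) {
    df <- utils::read.delim(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(df)))
        stop("ortholog map must have columns 'source' and 'target': ", path)
    if (anyDuplicated(df$source))
        stop("ortholog map has duplicated source genes: ", path)
    stats::setNames(df$target, df$source)
}

#' Read a ligand-receptor pair database
#'
#' CSV with columns \code{pair_id}, \code{ligand}, \code{receptor} and
#' optionally \code{source_annotation}. When an ortholog map is supplied
#' (e.g. human to mouse), both genes of every pair are translated; pairs
#' with any unmapped gene are dropped and counted in the returned object.
#'
#' @param path Path to the CSV file.
#' @param orthologMap Optional named character vector from
#'   [readOrthologMap()].
#' @return An [LRDatabase-class].
#' @export
readLRDatabase <- function(path, orthologMap = NULL) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("pair_id", "ligand", "receptor")
    if (!all(need %in% names(df)))
        stop("ligand-receptor table must have columns ",
             paste(need, collapse = ", "), ": ", path)
    if (is.null(df$source_annotation)) df$source_annotation <- ""
    df <- df[c("pair_id", "ligand", "receptor", "source_annotation")]
    nDropped <- 0L
    droppedPairs <- character()
    if (!is.null(orthologMap)) {
        lig <- unname(orthologMap[df$ligand])
        rec <- unname(orthologMap[df$receptor])
        bad <- is.na(lig) | is.na(rec)
        nDropped <- sum(bad)
        droppedPairs <- df$pair_id[bad]
        df <- df[!bad, , drop = FALSE]
        df$ligand <- lig[!bad]
        df$receptor <- rec[!bad]
    }
    if (!nrow(df))
        stop("ligand-receptor database is empty after ortholog mapping: ",
             path)
    LRDatabase(df, nDropped, droppedPairs)
}

#' Write a ligand-receptor database as CSV
#'
#' @param db An [LRDatabase-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeLRDatabase <- function(db, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(db@pairs, path, quote = FALSE, row.names = FALSE)
    invisible(path)
}
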