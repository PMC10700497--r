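#' Permutation configuration for ligand-receptor testing
#'
#' @param nPermutations Number of label permutations B (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param shuffleScope \code{"joint_type_time"} (default): the
#'   (cell-type, time-point) label pairs are shuffled jointly across all
#'   cells, so the null mixes time points — the literal reading of
#'   "shuffled the cell-type and time-point labels".
#'   \code{"within_time"}: cell-type labels are shuffled within each time
#'   point, keeping the time structure fixed.
#' @param pRule \code{"plain"}: p = (number of null scores >= observed)/B.
#'   \code{"add_one"}: p = (1 + count)/(1 + B), which avoids p = 0.
#' @return A validated list of class \code{PermutationConfig}.
#' @export
permConfig <- function(nPermutations = 1000L, seed = 1L,
                       shuffleScope = c("joint_type_time", "within_time"),
                       pRule = c("plain", "add_one")) {
    if (nPermutations < 1) stop("nPermutations must be >= 1")
    cfg <- list(nPermutations = as.integer(nPermutations),
                seed = as.integer(seed),
                shuffleScope = match.arg(shuffleScope),
                pRule = match.arg(pRule))
    class(cfg) <- "PermutationConfig"
    cfg
}

#' Ligand-receptor interaction score
#'
#' The interaction score of a (ligand, receptor) pair between a sender and
#' a receiver cell type at one time point: the mean of (i) the average
#' log-normalized ligand expression over the sender's cells and (ii) the
#' average log-normalized receptor expression over the receiver's cells,
#' zeros included in both averages. A gene absent from the matrix
#' contributes 0 and raises a warning.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param labels Cell-type label per observation.
#' @param timePoints Time-point label per observation.
#' @param ligand,receptor Gene symbols of the pair.
#' @param sender,receiver Cell types supplying the ligand and the receptor.
#' @param t The time point evaluated.
#' @return The score, or \code{NA} if either type has no cell at \code{t}
#'   (combination not evaluable).
#' @export
lrScore <- function(expr, labels, timePoints, ligand, receptor,
                    sender, receiver, t) {
    X <- exprValues(expr)
    sIdx <- which(labels == sender & timePoints == t)
    rIdx <- which(labels == receiver & timePoints == t)
    if (!length(sIdx) || !length(rIdx)) return(NA_real_)
    gv <- function(gene, idx) {
        if (!gene %in% rownames(X)) {
            warning("gene '", gene, "' absent from expression matrix; ",
                    "contributes 0")
            return(0)
        }
        mean(X[gene, idx])
    }
    (gv(ligand, sIdx) + gv(receptor, rIdx)) / 2
}

#' Empirical permutation p value
#'
#' One-sided, large scores significant; ties count as >= (conservative).
#'
#' @param observed Observed score.
#' @param nullScores Vector of null scores.
#' @param pRule \code{"plain"} or \code{"add_one"} (see [permConfig()]).
#' @return The empirical p value in [0, 1].
#' @export
empiricalP <- function(observed, nullScores, pRule = c("plain", "add_one")) {
    pRule <- match.arg(pRule)
    if (!length(nullScores)) stop("nullScores must be non-empty")
    cnt <- sum(nullScores >= observed)
    B <- length(nullScores)
    if (pRule == "plain") cnt / B else (1 + cnt) / (1 + B)
}

# Shared permutation machinery. For a fixed stratification of cells into
# (type, time) groups, computes the observed group-mean matrix and then
# calls fun(M, b) once per permutation with the permuted group-mean matrix
# (groups x genes, rows in sorted group order — sizes are preserved by
# construction, so row order and dimensions never change). All pairs
# evaluated on the same data share this single permutation stream: every
# permutation scores all combinations at once.
.permApply <- function(X, grp, cfg, timePoints, fun) {
    Et <- as.matrix(Matrix::t(X))  # cells x genes
    nCells <- nrow(Et)
    gl <- sort(unique(grp))
    f <- factor(grp, levels = gl)
    sizes <- tabulate(f, nbins = length(gl))
    obsMeans <- rowsum(Et, f) / sizes
    set.seed(cfg$seed)
    for (b in seq_len(cfg$nPermutations)) {
        if (cfg$shuffleScope == "joint_type_time") {
            fperm <- f[sample.int(nCells)]
        } else {
            fperm <- f
            for (tv in unique(timePoints)) {
                idx <- which(timePoints == tv)
                fperm[idx] <- f[idx][sample.int(length(idx))]
            }
        }
        fun(rowsum(Et, fperm) / sizes, b)
    }
    obsMeans
}

#' Permutation null for a single ligand-receptor combination
#'
#' Returns the full vector of null interaction scores obtained by
#' shuffling the (cell-type, time-point) labels \code{cfg$nPermutations}
#' times and recomputing [lrScore()] after each shuffle. Group sizes are
#' preserved by construction. Deterministic given \code{cfg$seed}.
#'
#' @inheritParams lrScore
#' @param cfg A [permConfig()] object.
#' @return Numeric vector of length \code{cfg$nPermutations}.
#' @export
permutationNull <- function(expr, labels, timePoints, ligand, receptor,
                            sender, receiver, t, cfg = permConfig()) {
    X <- exprValues(expr)
    genes <- intersect(unique(c(ligand, receptor)), rownames(X))
    Xs <- X[genes, , drop = FALSE]
    grp <- paste(labels, timePoints, sep = "\r")
    sKey <- paste(sender, t, sep = "\r")
    rKey <- paste(receiver, t, sep = "\r")
    pull <- function(M, key, gene) {
        if (!gene %in% colnames(M) || !key %in% rownames(M)) 0
        else M[key, gene]
    }
    out <- numeric(cfg$nPermutations)
    .permApply(Xs, grp, cfg, timePoints, function(M, b)
        out[b] <<- (pull(M, sKey, ligand) + pull(M, rKey, receptor)) / 2)
    out
}

#' Score all ligand-receptor pairs across cell-type pairs and time points
#'
#' Evaluates every (pair, sender, receiver, time point) combination: the
#' observed interaction score, a permutation null obtained by shuffling the
#' (cell-type, time-point) labels — one shared stream of
#' \code{cfg$nPermutations} shuffles scores all combinations, so every pair
#' is compared against the same permutations — the empirical p, and a BH
#' adjustment across all records.
#'
#' @inheritParams lrScore
#' @param lrdb An [LRDatabase-class].
#' @param cfg A [permConfig()] object.
#' @param senders,receivers Optional restriction of the sender / receiver
#'   cell types evaluated (default: all observed types).
#' @return An [InteractionTable-class]. Combinations with no cells of a
#'   type at a time point are not evaluable and are excluded.
#' @export
interactionTable <- function(expr, labels, timePoints, lrdb,
                             cfg = permConfig(), senders = NULL,
                             receivers = NULL) {
    stopifnot(is(expr, "ExpressionMatrix"), is(lrdb, "LRDatabase"))
    labels <- as.character(labels)
    timePoints <- as.character(timePoints)
    if (length(labels) != ncol(expr) || length(timePoints) != ncol(expr))
        stop("labels and timePoints must have one entry per observation")
    pairs <- lrPairs(lrdb)
    types <- sort(unique(labels))
    tps <- unique(timePoints)
    if (is.null(senders)) senders <- types
    if (is.null(receivers)) receivers <- types
    X <- exprValues(expr)
    genes <- unique(c(pairs$ligand, pairs$receptor))
    missing <- setdiff(genes, rownames(X))
    if (length(missing))
        warning(length(missing), " ligand/receptor gene(s) absent from the",
                " expression matrix; they contribute 0 to scores")
    present <- intersect(genes, rownames(X))
    Xs <- X[present, , drop = FALSE]
    grp <- paste(labels, timePoints, sep = "\r")
    gl <- sort(unique(grp))

    # expand the record grid, keep evaluable combinations only
    grid <- expand.grid(i = seq_len(nrow(pairs)), sender = senders,
                        receiver = receivers, time_point = tps,
                        stringsAsFactors = FALSE)
    sKey <- paste(grid$sender, grid$time_point, sep = "\r")
    rKey <- paste(grid$receiver, grid$time_point, sep = "\r")
    evaluable <- sKey %in% gl & rKey %in% gl
    grid <- grid[evaluable, , drop = FALSE]
    sKey <- sKey[evaluable]; rKey <- rKey[evaluable]
    if (!nrow(grid)) stop("no evaluable (sender, receiver, time) combination")

    sRow <- match(sKey, gl)
    rRow <- match(rKey, gl)
    ligIdx <- match(pairs$ligand[grid$i], present)
    recIdx <- match(pairs$receptor[grid$i], present)
    valAt <- function(M, row, col) {
        v <- rep(0, length(row))
        ok <- !is.na(col)
        v[ok] <- M[cbind(row[ok], col[ok])]
        v
    }
    B <- cfg$nPermutations
    nullMat <- matrix(0, nrow = B, ncol = nrow(grid))
    obsM <- .permApply(Xs, grp, cfg, timePoints, function(M, b)
        nullMat[b, ] <<- (valAt(M, sRow, ligIdx) +
                          valAt(M, rRow, recIdx)) / 2)
    observed <- (valAt(obsM, sRow, ligIdx) + valAt(obsM, rRow, recIdx)) / 2
    geCount <- colSums(nullMat >= matrix(observed, nrow = B,
                                         ncol = nrow(grid), byrow = TRUE))
    pEmp <- if (cfg$pRule == "plain") geCount / B else
        (1 + geCount) / (1 + B)
    q <- apply(nullMat, 2, stats::quantile, probs = c(0.95, 0.99),
               names = FALSE)
    rec <- data.frame(
        pair_id = pairs$pair_id[grid$i],
        ligand = pairs$ligand[grid$i], receptor = pairs$receptor[grid$i],
        sender = grid$sender, receiver = grid$receiver,
        time_point = grid$time_point, score = observed,
        null_mean = colMeans(nullMat), null_q95 = q[1, ],
        null_q99 = q[2, ], n_perm = B, p_empirical = pEmp,
        p_adjusted = bhAdjust(pEmp), stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    new("InteractionTable", records = rec, config = unclass(cfg))
}

#' Count significant interactions per receiver and time point
#'
#' @param it An [InteractionTable-class].
#' @param threshold Significance threshold (default 0.05).
#' @param adjusted Count on the BH-adjusted p (default) or the raw
#'   empirical p.
#' @return data.frame with columns \code{receiver}, \code{time_point},
#'   \code{n_significant}, ordered by receiver then time point (input time
#'   order preserved).
#' @export
significantInteractionCounts <- function(it, threshold = 0.05,
                                         adjusted = TRUE) {
    r <- interactions(it)
    p <- if (adjusted) r$p_adjusted else r$p_empirical
    sig <- r[p < threshold, , drop = FALSE]
    tps <- unique(r$time_point)
    out <- expand.grid(receiver = sort(unique(r$receiver)),
                       time_point = tps, stringsAsFactors = FALSE)
    out$n_significant <- mapply(function(rc, tp)
        sum(sig$receiver == rc & sig$time_point == tp),
        out$receiver, out$time_point)
    out[order(out$receiver), ]
}

#' Write an interaction table and its significance summary
#'
#' @param it An [InteractionTable-class].
#' @param path Output TSV for the records.
#' @param summaryPath Optional TSV for the per-(receiver, time) counts.
#' @param threshold Significance threshold for the summary.
#' @return Invisibly, \code{path}.
#' @export
writeInteractionTable <- function(it, path, summaryPath = NULL,
                                  threshold = 0.05) {
    writeResultTSV(interactions(it), path)
    if (!is.null(summaryPath))
        writeResultTSV(significantInteractionCounts(it, threshold),
                       summaryPath)
    invisible(path)
}
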