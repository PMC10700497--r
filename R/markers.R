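#' Group-versus-rest Wilcoxon rank-sum test per gene
#'
#' For every gene, compares log-normalized expression of the observations in
#' \code{group} against all remaining observations with a two-sided Wilcoxon
#' rank-sum test. P values use the normal approximation with tie correction
#' and continuity correction; when both groups have at most 8 members the
#' exact permutation distribution is enumerated instead. P values are
#' computed in log space so thresholds far below double underflow (e.g.
#' 1e-20 on adjusted scales down to ~1e-300 and beyond) remain decidable via
#' the \code{p_log10} column.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param labels Character vector of group labels, one per observation
#'   (column order of \code{expr}).
#' @param group The label defining the test group; must occur in
#'   \code{labels}.
#' @param method \code{"auto"} (exact when both groups have at most 8
#'   members, approximation otherwise), \code{"exact"} or \code{"approx"}.
#' @return data.frame (one row per gene): \code{gene}, \code{group_mean},
#'   \code{rest_mean}, \code{avg_log_fc}, \code{statistic} (Mann-Whitney U),
#'   \code{p_value}, \code{p_log10}, \code{p_adjusted} (BH),
#'   \code{pct_in_group}, \code{pct_in_rest}.
#' @export
wilcoxonGroupVsRest <- function(expr, labels, group,
                                method = c("auto", "exact", "approx")) {
    method <- match.arg(method)
    idx <- .deIndices(expr, labels, group)
    X <- as.matrix(exprValues(expr))
    n1 <- length(idx$grp); n2 <- length(idx$rest); n <- n1 + n2
    if (method == "exact" && (n1 > 10 || n2 > 10))
        stop("exact enumeration is limited to groups of at most 10")
    if (method == "exact" || (method == "auto" && n1 <= 8 && n2 <= 8)) {
        stat <- p <- numeric(nrow(X))
        for (g in seq_len(nrow(X))) {
            e <- .wilcoxExact(X[g, c(idx$grp, idx$rest)], seq_len(n1))
            stat[g] <- e$U; p[g] <- e$p
        }
        plog10 <- log10(p)
    } else {
        rk <- t(apply(X[, c(idx$grp, idx$rest), drop = FALSE], 1, rank))
        R1 <- rowSums(rk[, seq_len(n1), drop = FALSE])
        U <- R1 - n1 * (n1 + 1) / 2
        muU <- n1 * n2 / 2
        tieSum <- apply(rk, 1, function(r) {
            tt <- tabulate(match(r, unique(r)))
            sum(tt^3 - tt)
        })
        sigma2 <- n1 * n2 / 12 * ((n + 1) - tieSum / (n * (n - 1)))
        z <- pmax(abs(U - muU) - 0.5, 0) / sqrt(pmax(sigma2, 0))
        logp <- log(2) + stats::pnorm(-z, log.p = TRUE)
        logp[sigma2 == 0] <- 0  # fully tied: no signal
        logp <- pmin(logp, 0)
        stat <- U
        plog10 <- logp / log(10)
        p <- exp(logp)
    }
    .deResult(X, idx, stat, p, plog10)
}

# Exact two-sided rank-sum p by enumeration of all C(n, n1) group
# assignments (midranks, so ties are handled); p = min(1, 2 min(P(W <= w),
# P(W >= w))).
.wilcoxExact <- function(x, grpPos) {
    n <- length(x); n1 <- length(grpPos)
    rk <- rank(x)
    w <- sum(rk[grpPos])
    combs <- utils::combn(n, n1)
    W <- colSums(matrix(rk[combs], nrow = n1))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(W <= w + eps), mean(W >= w - eps)))
    list(U = w - n1 * (n1 + 1) / 2, p = p)
}

.deIndices <- function(expr, labels, group) {
    stopifnot(is(expr, "ExpressionMatrix"))
    if (length(labels) != ncol(expr))
        stop("labels must have one entry per observation")
    if (!group %in% labels)
        stop("group '", group, "' absent from labels")
    grp <- which(labels == group)
    rest <- which(labels != group)
    if (length(grp) < 2 || length(rest) < 2)
        stop("group and rest must each have at least 2 observations")
    list(grp = grp, rest = rest)
}

.deResult <- function(X, idx, stat, p, plog10, degenerate = NULL) {
    gm <- rowMeans(X[, idx$grp, drop = FALSE])
    rm_ <- rowMeans(X[, idx$rest, drop = FALSE])
    res <- data.frame(
        gene = rownames(X), group_mean = gm, rest_mean = rm_,
        avg_log_fc = gm - rm_, statistic = stat, p_value = p,
        p_log10 = plog10, p_adjusted = bhAdjust(p),
        pct_in_group = rowMeans(X[, idx$grp, drop = FALSE] > 0),
        pct_in_rest = rowMeans(X[, idx$rest, drop = FALSE] > 0),
        row.names = NULL)
    if (!is.null(degenerate)) res$degenerate <- degenerate
    res
}

#' Group-versus-rest t test per gene
#'
#' Two-sided t test of \code{group} against the rest for every gene.
#' Welch's unequal-variance form is the default (group sizes and variances
#' are rarely comparable in a cluster-versus-rest design); a pooled-variance
#' Student form is available. Genes with zero variance in both groups and
#' equal means are flagged degenerate and given p = 1 by convention. P
#' values are computed in log space (\code{p_log10}) so thresholds such as
#' 1e-20 remain decidable after underflow.
#'
#' @inheritParams wilcoxonGroupVsRest
#' @param var \code{"welch"} (default) or \code{"pooled"}.
#' @return data.frame as in [wilcoxonGroupVsRest()], with \code{statistic}
#'   the t statistic, plus a \code{degenerate} flag column.
#' @export
ttestGroupVsRest <- function(expr, labels, group,
                             var = c("welch", "pooled")) {
    var <- match.arg(var)
    idx <- .deIndices(expr, labels, group)
    X <- exprValues(expr)
    n1 <- length(idx$grp); n2 <- length(idx$rest)
    s1 <- Matrix::rowSums(X[, idx$grp, drop = FALSE])
    q1 <- Matrix::rowSums(X[, idx$grp, drop = FALSE]^2)
    s2 <- Matrix::rowSums(X[, idx$rest, drop = FALSE])
    q2 <- Matrix::rowSums(X[, idx$rest, drop = FALSE]^2)
    m1 <- s1 / n1; m2 <- s2 / n2
    v1 <- pmax(q1 - n1 * m1^2, 0) / (n1 - 1)
    v2 <- pmax(q2 - n2 * m2^2, 0) / (n2 - 1)
    if (var == "welch") {
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
        vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se2 <- vp * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2, length(se2))
    }
    diff <- m1 - m2
    tstat <- ifelse(se2 > 0, diff / sqrt(se2),
                    ifelse(diff == 0, 0, sign(diff) * Inf))
    degenerate <- se2 == 0 & diff == 0
    df[se2 == 0] <- n1 + n2 - 2  # unused except to keep pt() defined
    logp <- log(2) + stats::pt(-abs(tstat), df, log.p = TRUE)
    logp[degenerate] <- 0
    logp <- pmin(logp, 0)
    res <- .deResult(as.matrix(X), idx, tstat, exp(logp), logp / log(10),
                     degenerate = degenerate)
    attr(res, "var") <- var
    res
}

#' Average log fold change, group versus rest
#'
#' Difference of mean log-normalized expression (natural log scale):
#' \code{mean(group) - mean(rest)} per gene.
#'
#' @inheritParams wilcoxonGroupVsRest
#' @return Named numeric vector, one value per gene.
#' @export
avgLogFC <- function(expr, labels, group) {
    idx <- .deIndices(expr, labels, group)
    X <- exprValues(expr)
    stats::setNames(
        Matrix::rowMeans(X[, idx$grp, drop = FALSE]) -
            Matrix::rowMeans(X[, idx$rest, drop = FALSE]),
        rownames(X))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: adjusted value attached to the original
#' position, monotone in the sorted order, capped at 1.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Adjusted p values, same order as the input.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1] with no NAs")
    stats::p.adjust(p, method = "BH")
}

#' Build thresholded marker gene sets for MIA
#'
#' Runs the chosen group-versus-rest test for every label level and keeps,
#' per level, the genes with positive average log fold change (at least
#' \code{logfcMin} when given) and p value strictly below
#' \code{pThreshold} (BH-adjusted when \code{adjust = TRUE}). The
#' positive-logFC filter on a two-sided test selects genes with
#' statistically higher expression in the group. Thresholding uses the
#' log-space p, so cutoffs below double underflow still partition genes
#' correctly.
#'
#' @inheritParams wilcoxonGroupVsRest
#' @param test \code{"ttest"} or \code{"wilcoxon"}.
#' @param pThreshold Strict upper bound on the (adjusted) p value.
#' @param adjust Threshold the BH-adjusted p instead of the raw p.
#' @param logfcMin Optional minimum average log fold change.
#' @param modality Provenance tag (\code{"scRNA"} or \code{"ST"}).
#' @param allowEmpty Permit an entirely empty collection (default errors).
#' @return A [GeneSetCollection-class].
#' @export
buildGeneSets <- function(expr, labels, test = c("ttest", "wilcoxon"),
                          pThreshold = 1e-20, adjust = FALSE,
                          logfcMin = NULL, modality = "scRNA",
                          allowEmpty = FALSE) {
    test <- match.arg(test)
    levels <- sort(unique(labels))
    tab <- table(labels)
    if (any(tab < 2))
        stop("every label level needs at least 2 observations; violated by: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    sets <- list()
    for (lv in levels) {
        de <- if (test == "ttest") ttestGroupVsRest(expr, labels, lv)
              else wilcoxonGroupVsRest(expr, labels, lv)
        if (adjust) {
            keep <- de$p_adjusted < pThreshold
        } else {
            keep <- de$p_log10 < log10(pThreshold)
        }
        keep <- keep & de$avg_log_fc > 0
        if (!is.null(logfcMin)) keep <- keep & de$avg_log_fc >= logfcMin
        sets[[lv]] <- sort(de$gene[keep])
    }
    if (!allowEmpty && all(lengths(sets) == 0))
        stop("all gene sets are empty at p < ", pThreshold,
             "; use allowEmpty = TRUE to override")
    info <- data.frame(set = levels, modality = modality, test = test,
                       p_threshold = pThreshold, adjusted = adjust,
                       logfc_min = if (is.null(logfcMin)) NA_real_
                                   else logfcMin,
                       n_genes = unname(lengths(sets)[levels]),
                       stringsAsFactors = FALSE)
    new("GeneSetCollection", sets = sets[levels], info = info)
}

#' Write a GeneSetCollection in GMT format
#'
#' One line per set: name, provenance description, then member genes,
#' tab-separated.
#'
#' @param gsc A [GeneSetCollection-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(gsc, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    info <- setInfo(gsc)
    desc <- sprintf("%s|%s|p<%g%s", info$modality, info$test,
                    info$p_threshold,
                    ifelse(info$adjusted, "|adjusted", ""))
    lines <- vapply(seq_along(gsc@sets), function(i)
        paste(c(names(gsc@sets)[i], desc[i], gsc@sets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a GMT file into a GeneSetCollection
#'
#' @param path Path to a GMT file.
#' @return A [GeneSetCollection-class] (provenance columns set to NA).
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, "", 1)
    info <- data.frame(set = names(sets), modality = NA_character_,
                       test = NA_character_, p_threshold = NA_real_,
                       adjusted = NA, logfc_min = NA_real_,
                       n_genes = unname(lengths(sets)),
                       stringsAsFactors = FALSE)
    new("GeneSetCollection", sets = sets, info = info)
}
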