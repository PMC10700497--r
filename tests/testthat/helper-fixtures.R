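# Fixtures are built in code at test time; nothing is stored on disk.

# 3 genes x 2 observations with two nonzeros: (g1,b1)=5, (g3,b2)=2
tinyCountMatrix <- function(obsKind = "cell") {
    m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
                              dims = c(3, 2),
                              dimnames = list(c("g1", "g2", "g3"),
                                              c("b1", "b2")))
    CountMatrix(m, obsKind)
}

# ExpressionMatrix straight from a dense matrix of log values
exprFromMatrix <- function(x, obsKind = "cell", S = 1e4) {
    new("ExpressionMatrix",
        values = as(as(as(Matrix::Matrix(x, sparse = TRUE), "dMatrix"),
                       "generalMatrix"), "CsparseMatrix"),
        scaleFactor = S, logBase = exp(1), obsKind = obsKind)
}

# CountMatrix from a dense integer matrix
countsFromMatrix <- function(x, obsKind = "cell") {
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("b%02d", seq_len(ncol(x)))
    CountMatrix(Matrix::Matrix(x, sparse = TRUE), obsKind)
}

# 100-cell fixture with one known violation of each printed QC rule and a
# planted top-6% doublet block; survivors are derivable by hand.
# Genes: GeneA (ordinary), mt-1 (mitochondrial), Hb_1 (hemoglobin).
# Hand-derived outcome:
#   c_mito   mito fraction 0.15  -> dropped (rule mito)
#   c_low    total 150           -> dropped (rule umi_min)
#   c_high   total 10,001        -> dropped (rule umi_max)
#   c_hb     hb fraction 0.02    -> dropped (rule hb)
#   c_b1..c_b4 exact boundaries (0.10 mito, 200 umi, 10,000 umi, 0.01 hb)
#            -> kept (strict inequalities)
#   remaining 92 clean cells     -> kept
# After qcCells 96 cells remain; doublet removal takes round(0.06*96) = 6:
# the six cells c_d1..c_d6 carry score 0.9, everything else 0.1.
qcFixture100 <- function() {
    mkcell <- function(total, mitoFrac = 0.04, hbFrac = 0.005) {
        mt <- round(total * mitoFrac)
        hb <- round(total * hbFrac)
        c(GeneA = total - mt - hb, `mt-1` = mt, Hb_1 = hb)
    }
    cells <- list(
        c_mito = mkcell(1000, mitoFrac = 0.15),
        c_low  = mkcell(150),
        c_high = mkcell(10001),
        c_hb   = mkcell(1000, hbFrac = 0.02),
        c_b1   = mkcell(1000, mitoFrac = 0.10),
        c_b2   = mkcell(200),
        c_b3   = mkcell(10000),
        c_b4   = mkcell(1000, hbFrac = 0.01))
    for (i in seq_len(92))
        cells[[sprintf("c_%03d", i)]] <- mkcell(1000)
    x <- do.call(cbind, cells)
    dNames <- sprintf("c_d%d", 1:6)
    # rename six clean cells as the doublet block
    idx <- match(sprintf("c_%03d", 1:6), colnames(x))
    cn <- colnames(x); cn[idx] <- dNames
    colnames(x) <- cn
    m <- countsFromMatrix(x, "cell")
    score <- stats::setNames(rep(0.1, 100), cn)
    score[dNames] <- 0.9
    obs <- data.frame(obs_id = cn, time_point = "d5",
                      doublet_score = unname(score),
                      stringsAsFactors = FALSE)
    expectedSurvivors <- setdiff(cn, c("c_mito", "c_low", "c_high", "c_hb",
                                       dNames))
    list(counts = m, obs = obs, mito = "mt-1", hb = "Hb_1",
         survivors = expectedSurvivors)
}

# brute-force BH step-up, literally adj_(i) = min(1, min_{j >= i} m p_(j)/j)
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
        min(1, min(vapply(i:m, function(j) m * ps[j] / j, 0))), 0)
    out <- numeric(m)
    out[o] <- adj
    out
}

# closed-form upper-tail hypergeometric by direct summation of the
# probability mass (independent of phyper)
chooseSumUpperTail <- function(k, m, n, N) {
    ks <- k:min(m, n)
    if (k == 0) return(1)
    sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# truly exhaustive enumeration of all C(N, n) draws (small N only)
enumUpperTail <- function(k, m, n, N) {
    marked <- seq_len(m)
    draws <- utils::combn(N, n)
    mean(colSums(matrix(draws %in% marked, nrow = n)) >= k)
}

# default-scale (study-condition) scRNA simulation, generated once per
# test run and shared
.simCache <- new.env(parent = emptyenv())
defaultScrna <- function() {
    if (is.null(.simCache$sc)) .simCache$sc <- generateScrna(simConfig())
    .simCache$sc
}

# small simulation config used across tests (kept light)
smallSimConfig <- function(seed = 1L, ...) {
    simConfig(seed = seed, nCellsPerTimepoint = 125L, nGenes = 600L,
              nMarkersPerType = 10L, nSpots = 120L, ...)
}
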