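test_that("cell filters apply the printed thresholds strictly", {
    # columns: mito fractions 0.15 (drop) / 0.10 (keep);
    # totals 150 (drop), 200 (keep), 10000 (keep), 10001 (drop)
    x <- cbind(
        m15 = c(850, 150, 0), m10 = c(900, 100, 0),
        u150 = c(140, 10, 0), u200 = c(190, 10, 0),
        u10k = c(9990, 10, 0), u10k1 = c(9991, 10, 0))
    rownames(x) <- c("GeneA", "mt-1", "Hb_1")
    m <- countsFromMatrix(x, "cell")
    obs <- data.frame(obs_id = colnames(x))
    out <- qcCells(m, obs, qcParams(), "mt-1", "Hb_1")
    expect_setequal(obsIds(out$counts), c("m10", "u200", "u10k"))
    expect_identical(droppedIds(out$report, "mito"), "m15")
    expect_setequal(droppedIds(out$report, "umi_min"), "u150")
    expect_setequal(droppedIds(out$report, "umi_max"), "u10k1")
})

test_that("one violation per rule is attributed to that rule", {
    x <- cbind(
        clean = c(960, 30, 10),
        mito = c(800, 190, 10),
        low = c(100, 5, 1),
        high = c(10500, 400, 20),
        hb = c(940, 30, 30))
    rownames(x) <- c("GeneA", "mt-1", "Hb_1")
    m <- countsFromMatrix(x, "cell")
    obs <- data.frame(obs_id = colnames(x))
    out <- qcCells(m, obs, qcParams(), "mt-1", "Hb_1")
    s <- qcSummary(out$report)
    expect_identical(unname(s[c("mito", "umi_min", "umi_max", "hb")]),
                     rep(1L, 4))
    expect_identical(obsIds(out$counts), "clean")
    expect_identical(s[["n_in"]] - sum(s[c("mito", "umi_min", "umi_max",
                                           "hb")]), s[["n_out"]])
})

test_that("gene filter keeps genes seen in at least three cells", {
    # 10 genes: 4 below the threshold (0, 1, 2, 2 cells), 6 at or above
    x <- matrix(0L, nrow = 10, ncol = 5)
    x[1, ] <- 0L                      # all-zero
    x[2, 1] <- 1L                     # 1 cell
    x[3, 1:2] <- 1L; x[4, 1:2] <- 1L  # 2 cells
    for (g in 5:10) x[g, 1:3] <- 1L   # exactly 3 cells
    m <- countsFromMatrix(x, "cell")
    out <- qcGenes(m, qcParams())
    expect_equal(nrow(out$counts), 6L)
    expect_setequal(geneIds(out$counts), sprintf("g%02d", 5:10))
    expect_equal(qcSummary(out$report)[["min_cells"]], 4L)
})

test_that("doublet removal takes the top fraction by score, ties by barcode", {
    obs <- data.frame(obs_id = sprintf("b%03d", 1:100),
                      time_point = "d5",
                      doublet_score = c(rep(0.9, 6), rep(0.2, 94)))
    out <- qcDoublets(obs, qcParams())
    expect_setequal(setdiff(obs$obs_id, out$kept), sprintf("b%03d", 1:6))

    # all-equal scores: deterministic removal by barcode order
    obs$doublet_score <- 0.5
    out2 <- qcDoublets(obs, qcParams())
    expect_identical(setdiff(obs$obs_id, out2$kept), sprintf("b%03d", 1:6))

    obs$doublet_score <- NULL
    expect_error(qcDoublets(obs, qcParams()), "doublet_score")
})

test_that("planted doublet scores recover the truth doublet set exactly", {
    sc <- generateScrna(smallSimConfig())
    out <- qcDoublets(sc$obs, qcParams())
    removed <- setdiff(sc$obs$obs_id, out$kept)
    expect_setequal(removed, sc$truth@obs$obs_id[sc$truth@obs$is_doublet])
})

test_that("spot QC removes contaminant genes, excluded labels and weak spots", {
    # 20 spots: 3 low-UMI, 2 labelled outside the tissue, 15 clean
    ng <- 120
    x <- matrix(10L, nrow = ng, ncol = 20)
    rownames(x) <- c(sprintf("gene%03d", 1:115), "mt-1", "mt-2", "Rps_1",
                     "Rps_2", "Hb_1")
    colnames(x) <- sprintf("s%02d", 1:20)
    x[, 1:3] <- 0L; x[1:20, 1:3] <- 2L  # 40 UMIs, 20 genes
    m <- countsFromMatrix(x, "spot")
    obs <- data.frame(obs_id = colnames(x),
                      group_label = c(rep("tissue", 18), "outside",
                                      "outside"),
                      x = 1:20, y = 1)
    out <- qcSpots(m, obs, qcParams(excludeSpotLabels = "outside"),
                   mitoGenes = c("mt-1", "mt-2"),
                   riboGenes = c("Rps_1", "Rps_2"))
    expect_equal(ncol(out$counts), 15L)
    expect_setequal(out$removedGenes, c("mt-1", "mt-2", "Rps_1", "Rps_2"))
    expect_false(any(c("mt-1", "Rps_1") %in% geneIds(out$counts)))
    s <- qcSummary(out$report)
    expect_equal(s[["excluded_label"]], 2L)
    expect_equal(s[["spot_umi_min"]], 3L)
})

test_that("QC counters conserve and filters are idempotent and monotone", {
    sc <- generateScrna(smallSimConfig(seed = 11))
    classes <- simGeneClasses(smallSimConfig(seed = 11))
    p <- qcParams()
    out <- qcCells(sc$counts, sc$obs, p, classes$mito, classes$hb)
    s <- qcSummary(out$report)
    expect_equal(s[["n_in"]], sum(s[setdiff(names(s),
                                            c("n_in", "n_out"))]) +
                 s[["n_out"]])
    # idempotence
    out2 <- qcCells(out$counts, out$obs, p, classes$mito, classes$hb)
    expect_identical(obsIds(out2$counts), obsIds(out$counts))
    g1 <- qcGenes(out$counts, p)
    g2 <- qcGenes(g1$counts, p)
    expect_identical(geneIds(g2$counts), geneIds(g1$counts))
    # monotonicity: loosening a threshold never shrinks the output
    loose <- qcCells(sc$counts, sc$obs, qcParams(mitoMax = 0.5,
                                                 umiMin = 50),
                     classes$mito, classes$hb)
    expect_gte(ncol(loose$counts), ncol(out$counts))

    st <- generateSt(smallSimConfig(seed = 11))
    sp1 <- qcSpots(st$counts, st$obs, p, classes$mito, classes$ribo)
    sp2 <- qcSpots(sp1$counts, sp1$obs, p, classes$mito, classes$ribo)
    expect_identical(obsIds(sp2$counts), obsIds(sp1$counts))
})

test_that("log-normalization follows the stated spot and cell rules", {
    # spots with totals 100, 200, 300: S = median = 200
    x <- cbind(s1 = c(10, 90, 0), s2 = c(0, 200, 0), s3 = c(30, 270, 0))
    rownames(x) <- c("gA", "gB", "gC")
    em <- logNormalize(countsFromMatrix(x, "spot"), "spots")
    expect_equal(scaleFactor(em), 200)
    expect_equal(exprValues(em)["gA", "s1"], log(21))  # 10/100*200 = 20
    expect_equal(exprValues(em)["gC", "s1"], 0)        # zero stays zero

    # cells: S = 10,000; count 1 in a 10,000-total cell -> ln(2)
    y <- cbind(c1 = c(1, 9999))
    rownames(y) <- c("gA", "gB")
    ec <- logNormalize(countsFromMatrix(y, "cell"), "cells")
    expect_equal(exprValues(ec)["gA", "c1"], log(2))

    # strictly increasing in the count at fixed total
    z <- cbind(c1 = c(1, 2, 97))
    ez <- logNormalize(countsFromMatrix(z, "cell"), "cells")
    expect_true(exprValues(ez)[2, 1] > exprValues(ez)[1, 1])

    # zero-total observations must not reach normalization
    w <- cbind(c1 = c(1, 1), c2 = c(0, 0))
    expect_error(logNormalize(countsFromMatrix(w, "cell"), "cells"),
                 "zero-total")
})
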