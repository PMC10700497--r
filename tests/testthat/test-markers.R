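test_that("Wilcoxon exact enumeration matches hand-derived cases", {
    # one gene, values 1..4; group holds observations with values {1, 4}:
    # rank sum 5 equals its expectation over all C(4,2) assignments -> p = 1
    em <- exprFromMatrix(matrix(c(1, 2, 3, 4), nrow = 1,
                               dimnames = list("g", paste0("c", 1:4))))
    de <- wilcoxonGroupVsRest(em, c("A", "B", "B", "A"), "A")
    expect_equal(de$p_value, 1.0)

    # fully tied data carries no signal
    em2 <- exprFromMatrix(matrix(5, nrow = 1, ncol = 6,
                                 dimnames = list("g", paste0("c", 1:6))))
    de2 <- wilcoxonGroupVsRest(em2, rep(c("A", "B"), 3), "A")
    expect_equal(de2$p_value, 1.0)
})

test_that("Wilcoxon agrees with stats::wilcox.test on both paths", {
    set.seed(42)
    # exact path, no ties
    for (i in 1:20) {
        x <- abs(rnorm(10))  # expression values are non-negative
        labels <- rep(c("A", "B"), each = 5)
        em <- exprFromMatrix(matrix(x, nrow = 1,
                                    dimnames = list("g", paste0("c", 1:10))))
        ours <- wilcoxonGroupVsRest(em, labels, "A", method = "exact")
        ref <- stats::wilcox.test(x[1:5], x[6:10], exact = TRUE)
        expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
        expect_equal(ours$statistic, unname(ref$statistic))
    }
    # approximation path with ties, against the corrected normal test
    for (i in 1:10) {
        x <- sample(0:5, 40, replace = TRUE)
        labels <- rep(c("A", "B"), each = 20)
        em <- exprFromMatrix(matrix(x, nrow = 1,
                                    dimnames = list("g", paste0("c", 1:40))))
        ours <- wilcoxonGroupVsRest(em, labels, "A", method = "approx")
        ref <- suppressWarnings(
            stats::wilcox.test(x[1:20], x[21:40], exact = FALSE,
                               correct = TRUE))
        expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    }
})

test_that("normal approximation tracks exact enumeration for small groups", {
    # continuous data, group sizes 5-8: the regime in which both code
    # paths are reachable (below size 5 the implementation always
    # enumerates exactly, and the normal approximation is provably coarser
    # than 0.02 there even without ties)
    set.seed(7)
    for (i in 1:30) {
        n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
        x <- abs(rnorm(n1 + n2))
        labels <- c(rep("A", n1), rep("B", n2))
        em <- exprFromMatrix(matrix(x, nrow = 1,
                                    dimnames = list("g",
                                                    paste0("c",
                                                           seq_along(x)))))
        pe <- wilcoxonGroupVsRest(em, labels, "A", method = "exact")$p_value
        pa <- wilcoxonGroupVsRest(em, labels, "A",
                                  method = "approx")$p_value
        expect_lt(abs(pe - pa), 0.02)
    }
})

test_that("t test handles equal groups and degenerate genes by convention", {
    x <- rbind(flat = c(1, 2, 1, 2), zero = c(0, 0, 0, 0))
    em <- exprFromMatrix(x)
    colnames(x) <- obsIds(em)
    de <- ttestGroupVsRest(em, c("A", "A", "B", "B"), "A")
    expect_equal(de$statistic[1], 0)
    expect_equal(de$p_value[1], 1)
    expect_true(de$degenerate[2])
    expect_equal(de$p_value[2], 1)
})

test_that("Welch t matches stats::t.test per gene", {
    set.seed(13)
    X <- matrix(rnorm(50 * 30), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("c%02d", 1:30)))
    labels <- c(rep("A", 12), rep("B", 18))
    em <- exprFromMatrix(abs(X))
    de <- ttestGroupVsRest(em, labels, "A")
    for (g in c(1, 17, 50)) {
        ref <- stats::t.test(abs(X)[g, 1:12], abs(X)[g, 13:30])
        expect_equal(de$statistic[g], unname(ref$statistic),
                     tolerance = 1e-12)
        expect_equal(de$p_value[g], ref$p.value, tolerance = 1e-12)
    }
})

test_that("average log fold change is the difference of group means", {
    x <- matrix(c(2, 2, 1.5, 1.5), nrow = 1,
                dimnames = list("g", paste0("c", 1:4)))
    em <- exprFromMatrix(x)
    labels <- c("A", "A", "B", "B")
    expect_equal(unname(avgLogFC(em, labels, "A")), 0.5)
    expect_equal(unname(avgLogFC(em, labels, "B")), -0.5)  # antisymmetry
    same <- exprFromMatrix(matrix(c(1, 1, 1, 1), nrow = 1,
                                  dimnames = list("g", paste0("c", 1:4))))
    expect_equal(unname(avgLogFC(same, labels, "A")), 0)
})

test_that("BH adjustment matches its step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(1.0), 1.0)
    set.seed(5)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, bruteForceBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    expect_error(bhAdjust(c(0.5, -0.1)), "0, 1")
})

test_that("gene sets recover planted markers specifically", {
    cfg <- simConfig()  # the default study-scale conditions
    sc <- defaultScrna()
    expr <- logNormalize(sc$counts, "cells")
    classes <- simGeneClasses(cfg)
    sets <- buildGeneSets(expr, sc$obs$group_label, test = "ttest",
                          pThreshold = 1e-20, modality = "scRNA")
    for (ty in names(classes$markers)) {
        got <- geneSets(sets)[[ty]]
        planted <- classes$markers[[ty]]
        expect_gte(mean(planted %in% got), 0.9)
        others <- unlist(classes$markers[setdiff(names(classes$markers),
                                                 ty)])
        expect_length(intersect(got, others), 0L)
    }
})

test_that("region sets recover planted region programs", {
    cfg <- smallSimConfig()
    st <- generateSt(cfg)
    expr <- logNormalize(st$counts, "spots")
    classes <- simGeneClasses(cfg)
    sets <- buildGeneSets(expr, st$obs$group_label, test = "ttest",
                          pThreshold = 1e-3, modality = "ST")
    for (rg in names(classes$regionProgram)) {
        got <- geneSets(sets)[[rg]]
        expect_gte(mean(classes$regionProgram[[rg]] %in% got), 0.9)
    }
})

test_that("gene set construction honours its contracts", {
    cfg <- smallSimConfig()
    sc <- generateScrna(cfg)
    expr <- logNormalize(sc$counts, "cells")
    labels <- sc$obs$group_label
    # impossible threshold: every set empty -> error unless overridden
    expect_error(buildGeneSets(expr, labels, pThreshold = 0), "empty")

    # invariance to observation order and gene order
    sets <- buildGeneSets(expr, labels, pThreshold = 1e-20)
    set.seed(2)
    po <- sample(ncol(expr)); pg <- sample(nrow(expr))
    shuffled <- new("ExpressionMatrix",
                    values = exprValues(expr)[pg, po],
                    scaleFactor = scaleFactor(expr), logBase = exp(1),
                    obsKind = "cell")
    sets2 <- buildGeneSets(shuffled, labels[po], pThreshold = 1e-20)
    expect_identical(geneSets(sets), geneSets(sets2))

    # only positively enriched genes enter sets
    de <- ttestGroupVsRest(expr, labels, "TFC1")
    inset <- de$gene %in% geneSets(sets)$TFC1
    expect_true(all(de$avg_log_fc[inset] > 0))
})
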