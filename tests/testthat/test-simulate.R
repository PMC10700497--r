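test_that("configuration forces the data shape", {
    cfg <- simConfig(seed = 1, nCellsPerTimepoint = 100L, nGenes = 600L,
                     nMarkersPerType = 10L)
    sc <- generateScrna(cfg)
    expect_equal(ncol(sc$counts), 400L)  # 4 time points x 100 cells
    expect_equal(nrow(sc$counts), 600L)
    expect_identical(obsKind(sc$counts), "cell")
    expect_true(setequal(sc$obs$obs_id, obsIds(sc$counts)))

    st <- generateSt(cfg)
    expect_equal(ncol(st$counts), 454L)
    expect_identical(obsKind(st$counts), "spot")
})

test_that("doublets are planted exactly at round(rate * n) per time point", {
    cfg <- simConfig(seed = 3, nCellsPerTimepoint = 250L, nGenes = 600L,
                     nMarkersPerType = 10L, doubletRate = 0.06)
    sc <- generateScrna(cfg)
    # 4 x 250 = 1000 cells at rate 0.06: exactly 60 flagged
    expect_equal(sum(sc$truth@obs$is_doublet), 60L)
    perTp <- tapply(sc$truth@obs$is_doublet, sc$truth@obs$time_point, sum)
    expect_true(all(perTp == 15L))
    # planted scores separate: doublets 1, singlets < 0.5
    expect_true(all(sc$obs$doublet_score[sc$truth@obs$is_doublet] == 1))
    expect_true(all(sc$obs$doublet_score[!sc$truth@obs$is_doublet] < 0.5))
})

test_that("identical configuration reproduces byte-identical files", {
    cfg <- smallSimConfig(seed = 7)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    for (d in c(d1, d2)) {
        run <- generateScrna(cfg)
        writeCountMatrix(run$counts, file.path(d, "sc"))
        writeObsTable(as.data.frame(run$obs), file.path(d, "obs.tsv"))
        writeSyntheticTruth(run$truth, d)
    }
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         label = paste("file", f))
})

test_that("planted markers are recoverable (Wilcoxon p < 1e-6 at default effect)", {
    cfg <- smallSimConfig()  # 500 cells, log-effect 2.0
    sc <- generateScrna(cfg)
    expr <- logNormalize(sc$counts, "cells")
    labels <- sc$obs$group_label
    classes <- simGeneClasses(cfg)
    for (ty in c("TFC1", "Myeloid")) {
        de <- wilcoxonGroupVsRest(expr, labels, ty)
        rows <- de[de$gene %in% classes$markers[[ty]], ]
        expect_true(all(rows$p_value < 1e-6))
        expect_true(all(rows$avg_log_fc > 0))
    }
})

test_that("region programs separate central from peripheral spots", {
    cfg <- smallSimConfig()
    st <- generateSt(cfg)
    classes <- simGeneClasses(cfg)
    central <- st$truth@obs$true_region == "central"
    # a marker shared with the central program is elevated in central spots
    g <- classes$regionProgram$central[1]
    x <- as.numeric(counts(st$counts)[g, ])
    p <- stats::t.test(x[central], x[!central],
                       alternative = "greater")$p.value
    expect_lt(p, 0.01)
})

test_that("no shared genes makes the type-region correspondence unrecoverable", {
    cfg <- smallSimConfig(regionMarkerOverlap = 0)
    st <- generateSt(cfg)
    sc <- generateScrna(cfg)
    exprS <- logNormalize(st$counts, "spots")
    exprC <- logNormalize(sc$counts, "cells")
    regionSets <- buildGeneSets(exprS, st$obs$group_label, test = "ttest",
                                pThreshold = 1e-3, modality = "ST")
    typeSets <- buildGeneSets(exprC, sc$obs$group_label, test = "ttest",
                              pThreshold = 1e-10, modality = "scRNA",
                              allowEmpty = TRUE)
    map <- miaMap(typeSets, regionSets, geneIds(exprC), geneIds(exprS),
                  allowEmpty = TRUE)
    tb <- miaTable(map)
    planted <- sc$truth@typeRegion
    kPlanted <- mapply(function(ty, rg)
        tb$k[tb$type == ty & tb$region == rg],
        planted$type, planted$region)
    expect_true(all(kPlanted <= 1))
})

test_that("ligand-receptor channels are planted with their schedule", {
    cfg <- simConfig()  # default scale: ~75 receiver cells per time point
    sc <- defaultScrna()
    chan <- sc$truth@channels
    planted <- chan[chan$pair_id == "ch1", ]
    expect_identical(planted$sender, "Myeloid")
    expect_identical(planted$receiver, "TFC1")
    expect_equal(unlist(planted[paste0("effect_",
                                       c("d5", "d10", "d20", "d30"))],
                        use.names = FALSE),
                 c(2.0, 1.5, 1.0, 0.5))
    decoys <- chan[grepl("^decoy", chan$pair_id), ]
    expect_true(all(decoys[paste0("effect_",
                                  c("d5", "d10", "d20", "d30"))] == 0))

    # receptor mean log-expression in the receiver decays over time
    expr <- logNormalize(sc$counts, "cells")
    X <- exprValues(expr)
    recv <- sc$obs$group_label == "TFC1"
    means <- vapply(c("d5", "d10", "d20", "d30"), function(tp)
        mean(X["Rec1", recv & sc$obs$time_point == tp]), 0)
    expect_true(all(diff(means) < 0))
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(cellTypeFreqs = c(A = 0.5, B = 0.4)),
                 "sum to 1")
    expect_error(simConfig(doubletRate = 1), "doubletRate")
    expect_error(simConfig(nGenes = 100L), "too small")
    badChan <- list(list(pair_id = "x", ligand = "L", sender = "Nope",
                         receptor = "R", receiver = "TFC1",
                         effects = c(1, 1, 1, 1)))
    expect_error(simConfig(lrChannels = badChan), "sender/receiver")
})
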