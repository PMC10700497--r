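test_that("upper-tail hypergeometric matches hand-enumerated cases", {
    expect_equal(hypergeomUpperTail(0, 5, 5, 10), 1.0)
    # full overlap of two 5-sets in a 10-universe: 1 of C(10,5) = 252 draws
    expect_equal(hypergeomUpperTail(5, 5, 5, 10), 1 / 252,
                 tolerance = 1e-12)
    # two singletons in a 2-universe: overlap iff the same gene is drawn
    expect_equal(hypergeomUpperTail(1, 1, 1, 2), 0.5)

    expect_error(hypergeomUpperTail(3, 2, 2, 10), "k must lie")
    expect_error(hypergeomUpperTail(1, 5, 11, 10), "exceed")
    expect_error(hypergeomUpperTail(0.5, 1, 1, 2), "integers")
})

test_that("tails match exhaustive enumeration and the closed-form sum", {
    # truly exhaustive draw enumeration for small universes
    for (N in c(4, 6, 8)) {
        for (m in 1:N) for (n in 1:N) for (k in 0:min(m, n)) {
            expect_equal(hypergeomUpperTail(k, m, n, N),
                         enumUpperTail(k, m, n, N), tolerance = 1e-12,
                         label = sprintf("enum k=%d m=%d n=%d N=%d",
                                         k, m, n, N))
        }
    }
    # closed-form direct summation up to N = 12 (unit-scale sweep)
    for (N in c(10, 12)) {
        for (m in 1:N) for (n in 1:N) for (k in 0:min(m, n)) {
            expect_equal(hypergeomUpperTail(k, m, n, N),
                         chooseSumUpperTail(k, m, n, N),
                         tolerance = 1e-12)
        }
    }
})

test_that("enrichment and depletion tails are complementary and monotone", {
    set.seed(31)
    for (i in 1:200) {
        N <- sample(5:60, 1)
        m <- sample(1:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(m, n), 1)
        up <- hypergeomUpperTail(k, m, n, N)
        lower <- sum(choose(m, seq_len(k) - 1) *
                     choose(N - m, n - (seq_len(k) - 1))) / choose(N, n)
        expect_equal(up + lower, 1, tolerance = 1e-12)
    }
    # nonincreasing in k at fixed (m, n, N)
    ks <- 0:8
    ps <- hypergeomUpperTail(ks, 8, 10, 40)
    expect_true(all(diff(ps) <= 0))
})

test_that("miaPair computes scores, symmetry and background clipping", {
    bg <- sprintf("g%03d", 1:1000)
    a <- bg[1:5]; b <- bg[6:10]
    rec <- miaPair(a, b, bg)
    expect_equal(rec$k, 0L)
    expect_equal(rec$enrichment, 0)  # -log10(1) = 0

    # identical 5-sets in a 10-universe
    bg10 <- sprintf("g%03d", 1:10)
    recAA <- miaPair(bg10[1:5], bg10[1:5], bg10)
    expect_equal(recAA$enrichment, -log10(1 / 252), tolerance = 1e-9)

    # singleton case: both tails are 1/2, both scores -log10(1/2)
    rec11 <- miaPair("g001", "g001", c("g001", "g002"))
    expect_equal(rec11$p, 0.5)
    expect_equal(rec11$enrichment, -log10(0.5), tolerance = 1e-12)
    expect_equal(rec11$depletion, -log10(0.5), tolerance = 1e-12)

    # symmetry in the two sets
    set.seed(8)
    A <- sample(bg, 40); B <- sample(bg, 60)
    r1 <- miaPair(A, B, bg); r2 <- miaPair(B, A, bg)
    expect_equal(r1$k, r2$k)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$enrichment, r2$enrichment)
    expect_equal(r1$depletion, r2$depletion)

    # genes outside the background are dropped and counted, never added
    expect_warning(rec3 <- miaPair(c(A[1:5], "absent"), B, bg), "outside")
    expect_equal(rec3$n_outside_background, 1L)
    expect_equal(rec3$m, 5L)

    expect_error(miaPair(A, B, character()), "non-empty")
})

test_that("the MIA map covers all pairs and ignores set/gene ordering", {
    bg <- sprintf("g%03d", 1:500)
    ts <- new("GeneSetCollection",
              sets = list(T1 = bg[1:30], T2 = bg[31:60]),
              info = data.frame())
    rs <- new("GeneSetCollection",
              sets = list(R1 = bg[c(1:20, 61:70)], R2 = bg[101:140]),
              info = data.frame())
    map <- miaMap(ts, rs, backgroundMode = "custom", background = bg)
    tb <- miaTable(map)
    expect_equal(nrow(tb), 4L)
    expect_equal(tb$k[tb$type == "T1" & tb$region == "R1"], 20L)
    expect_equal(miaOverlaps(map)[["T1|R1"]], bg[1:20])

    # ordering invariance
    ts2 <- new("GeneSetCollection",
               sets = list(T2 = rev(bg[31:60]), T1 = sample(bg[1:30])),
               info = data.frame())
    map2 <- miaMap(ts2, rs, backgroundMode = "custom", background = bg)
    tb2 <- miaTable(map2)
    key <- function(d) d[order(d$type, d$region),
                         c("type", "region", "k", "p", "enrichment",
                           "depletion")]
    expect_equal(key(tb2), key(tb), ignore_attr = TRUE)

    # a 1x1 disjoint map yields a single zero-enrichment record
    one <- miaMap(new("GeneSetCollection", sets = list(A = bg[1]),
                      info = data.frame()),
                  new("GeneSetCollection", sets = list(B = bg[2]),
                      info = data.frame()),
                  backgroundMode = "custom", background = bg)
    expect_equal(nrow(miaTable(one)), 1L)
    expect_equal(miaTable(one)$enrichment, 0)

    # background must dominate the sets
    expect_error(miaMap(ts, rs, backgroundMode = "custom",
                        background = bg[1:10]),
                 "smaller than")
})
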