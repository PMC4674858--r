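# Pooled overlap percentages, stratification, and the one-sided
# two-sample proportion test.

test_that("TF-set overlap pools intersection and binding counts", {
    b <- mapFromList(list(t = c("g1", "g2")), "binding")
    k <- mapFromList(list(t = c("g2", "g3")), "knockout")
    res <- opForTfSet("t", b, k)
    expect_identical(opNumerator(res), 1L)
    expect_identical(opDenominator(res), 2L)
    expect_identical(opValue(res), 0.5)

    kDisjoint <- mapFromList(list(t = c("g8", "g9")), "knockout")
    expect_identical(opValue(opForTfSet("t", b, kDisjoint)), 0)

    expect_warning(res0 <- opForTfSet("absent", b, k), "undefined")
    expect_true(is.na(opValue(res0)))
    expect_identical(opDenominator(res0), 0L)
})

test_that("gene-set overlap pools the transposed sets", {
    b <- mapFromList(list(t1 = "g", t2 = "g", t3 = "g"), "binding")
    k <- mapFromList(list(t2 = "g"), "knockout")
    res <- opForGeneSet("g", b, k)
    expect_identical(opNumerator(res), 1L)
    expect_identical(opDenominator(res), 3L)
    expect_equal(opValue(res), 1 / 3)
    # a gene bound by no TF contributes 0/0
    res2 <- opForGeneSet(c("g", "unbound"), b, k)
    expect_identical(opDenominator(res2), 3L)
})

test_that("TF-set and gene-set overlap agree over the whole universe", {
    withr::local_seed(23)
    for (rep in 1:20) {
        b <- randomMap(6, 14, kind = "binding")
        k <- randomMap(6, 14, kind = "knockout")
        allTfs <- union(names(byRegulator(b)), names(byRegulator(k)))
        allGenes <- union(names(byGene(b)), names(byGene(k)))
        resT <- opForTfSet(allTfs, b, k)
        resG <- opForGeneSet(allGenes, b, k)
        expect_identical(opNumerator(resT), opNumerator(resG))
        expect_identical(opDenominator(resT), opDenominator(resG))
        # brute-force distinct-pair enumeration oracle
        expect_identical(opDenominator(resT), length(pairKeys(b)))
        expect_identical(opNumerator(resT),
                         sum(pairKeys(b) %in% pairKeys(k)))
    }
})

test_that("overlap of a TF-set union is the pair-weighted average", {
    withr::local_seed(41)
    for (rep in 1:10) {
        b <- randomMap(8, 12, kind = "binding")
        k <- randomMap(8, 12, kind = "knockout")
        tfs <- names(byRegulator(b))
        m1 <- tfs[seq_len(length(tfs) %/% 2)]
        m2 <- setdiff(tfs, m1)
        r1 <- opForTfSet(m1, b, k); r2 <- opForTfSet(m2, b, k)
        ru <- opForTfSet(c(m1, m2), b, k)
        expect_identical(opNumerator(ru), opNumerator(r1) + opNumerator(r2))
        expect_identical(opDenominator(ru),
                         opDenominator(r1) + opDenominator(r2))
    }
})

test_that("top/bottom strata slice floor(N*X/100) entities disjointly", {
    scores <- stats::setNames(1:10, sprintf("e%02d", 1:10))
    expect_identical(stratifyTopBottom(scores, 20, "top"),
                     c("e09", "e10"))
    expect_identical(stratifyTopBottom(scores, 20, "bottom"),
                     c("e01", "e02"))
    top <- stratifyTopBottom(scores, 50, "top")
    bottom <- stratifyTopBottom(scores, 50, "bottom")
    expect_length(top, 5); expect_length(bottom, 5)
    expect_length(intersect(top, bottom), 0)
    expect_setequal(c(top, bottom), names(scores))

    # all-tied scores still yield disjoint strata
    tied <- stats::setNames(rep(1, 10), sprintf("e%02d", 1:10))
    expect_length(intersect(stratifyTopBottom(tied, 50, "top"),
                            stratifyTopBottom(tied, 50, "bottom")), 0)

    expect_error(stratifyTopBottom(scores, 5), "stratum empty")
    expect_error(stratifyTopBottom(scores, 60), "\\(0, 50\\]")
    expect_error(stratifyTopBottom(stats::setNames(numeric(), character()),
                                   10), "non-empty")
})

test_that("proportion test reproduces the pooled z closed form", {
    g1 <- opForTfSet("t", mapFromList(list(t = sprintf("g%03d", 1:100))),
        mapFromList(list(t = sprintf("g%03d", 1:10)), "knockout"))
    g2 <- opForTfSet("t", mapFromList(list(t = sprintf("g%03d", 1:100))),
        mapFromList(list(t = sprintf("g%03d", 1:20)), "knockout"))
    res <- proportionTest(g1, g2, "group1_less")
    # frozen from the closed-form pooled z and numeric normal-tail oracle
    expect_equal(res@z, -1.9802950860, tolerance = 1e-9)
    expect_equal(res@pValue, 0.0238351903, tolerance = 1e-7)

    # equal proportions: z = 0, one-sided p = 0.5
    e1 <- opForTfSet("t", mapFromList(list(t = sprintf("g%02d", 1:50))),
        mapFromList(list(t = sprintf("g%02d", 1:5)), "knockout"))
    eq <- proportionTest(e1, g1, "group1_less")  # 5/50 vs 10/100
    expect_identical(eq@z, 0)
    expect_identical(eq@pValue, 0.5)

    # swapping groups with the mirrored alternative: same p, negated z
    sw <- proportionTest(g2, g1, "group1_greater")
    expect_equal(sw@z, -res@z)
    expect_identical(sw@pValue, res@pValue)

    # degenerate pooled proportion
    z1 <- opForTfSet("t", mapFromList(list(t = c("g1", "g2"))),
        mapFromList(list(t = "zz"), "knockout"))
    z2 <- opForTfSet("t", mapFromList(list(t = c("g3", "g4"))),
        mapFromList(list(t = "zz"), "knockout"))
    dg <- proportionTest(z1, z2, "group1_less")
    expect_true(dg@degenerate)
    expect_identical(dg@pValue, 0.5)
})

test_that("proportion-test p-values match independent oracles", {
    cases <- expand.grid(x1 = c(1, 5, 17), n1 = c(40, 173),
                         x2 = c(2, 11, 30), n2 = c(60, 400))
    mk <- function(x, n) new("OverlapResult", numerator = as.integer(x),
        denominator = as.integer(n), op = x / n, label = "case")
    for (i in seq_len(nrow(cases))) {
        with(cases[i, ], {
            g1 <- mk(x1, n1); g2 <- mk(x2, n2)
            for (alt in c("group1_less", "group1_greater")) {
                res <- proportionTest(g1, g2, alt)
                # numeric integration of the standard normal tail
                expect_equal(res@pValue,
                    oracleTailP(res@z, alt == "group1_less"),
                    tolerance = 1e-9)
            }
            # cross-check against the textbook test without continuity
            # correction (chi-square = z^2 route)
            # small expected counts trigger prop.test's approximation
            # warning; only the p-value equality is under test here
            pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                alternative = "less", correct = FALSE))
            expect_equal(proportionTest(g1, g2, "group1_less")@pValue,
                         pt$p.value, tolerance = 1e-12)
        })
    }
})

test_that("per-entity overlap table matches set arithmetic", {
    b <- mapFromList(list(t1 = c("g1", "g2"), t2 = "g1"), "binding")
    k <- mapFromList(list(t1 = "g2", t2 = "g3"), "knockout")
    u <- intersectUniverse(b, k)
    tfTab <- perEntityOverlap(b, k, u, "tf")
    expect_identical(tfTab$n_bound, c(2L, 1L))
    expect_identical(tfTab$n_overlap, c(1L, 0L))
    expect_equal(tfTab$op, c(0.5, 0))
    geneTab <- perEntityOverlap(b, k, u, "gene")
    g3row <- geneTab[geneTab$entity == "g3", ]
    expect_identical(g3row$n_bound, 0L)
    expect_true(is.na(g3row$op))
})
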