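# The synthetic-world generator: determinism, calibration, masking
# structure, ground truth, and file round-trips.

test_that("identical parameters produce byte-identical worlds", {
    w1 <- generateWorld(smallWorldParams(seed = 4L))
    w2 <- generateWorld(smallWorldParams(seed = 4L))
    expect_identical(records(w1@bindingTable), records(w2@bindingTable))
    expect_identical(records(w1@knockoutTable), records(w2@knockoutTable))
    expect_identical(termsByEntity(w1@annotationCatalog),
                     termsByEntity(w2@annotationCatalog))
    expect_identical(w1@propertyTables, w2@propertyTables)
    expect_identical(worldTruth(w1), worldTruth(w2))
    w3 <- generateWorld(smallWorldParams(seed = 5L))
    expect_false(identical(records(w1@bindingTable),
                           records(w3@bindingTable)))
})

test_that("ground truth recomputes every bound-pair effect probability", {
    w <- generateWorld(smallWorldParams(seed = 21L))
    tr <- worldTruth(w)
    keys <- strsplit(names(tr$boundPairProb), ":", fixed = TRUE)
    tf <- vapply(keys, `[[`, character(1), 1L)
    gene <- vapply(keys, `[[`, character(1), 2L)
    recomputed <- pmin(1, tr$base * tr$tfFactor[tf] * tr$geneFactor[gene])
    expect_equal(unname(tr$boundPairProb), unname(recomputed))
})

test_that("normalisation centres the expected overlap at the target", {
    for (seed in c(2L, 12L)) {
        w <- generateWorld(worldParams(seed = seed))
        tr <- worldTruth(w)
        # mean pre-draw effect probability over bound pairs = target OP
        # (up to the rare clipped pairs)
        expect_equal(mean(tr$boundPairProb),
                     worldParamsOf(w)@targetOverallOp, tolerance = 0.003)
    }
    # an explicit base rate is honoured unchanged
    wFixed <- generateWorld(smallWorldParams(seed = 2L,
        baseEffectProb = 0.02,
        geneClassEffectMultipliers = c(tata_containing = 1,
            nfr_containing = 1, ribosomal = 1),
        tfClassEffectMultipliers = c(chromatin_remodelling = 1),
        numericPropertyCoupling = c(expression = 0,
            transcriptional_plasticity = 0, n_bound_tfs = 0, n_tfbs = 0,
            mean_tfbs_tss_distance = 0),
        maskingStrength = 0))
    expect_identical(unique(unname(worldTruth(wFixed)$boundPairProb)), 0.02)
})

test_that("masking depresses paired-TF effect probabilities by its strength", {
    w <- generateWorld(worldParams(seed = 8L))
    tr <- worldTruth(w)
    tf <- vapply(strsplit(names(tr$boundPairProb), ":", fixed = TRUE),
                 `[[`, character(1), 1L)
    pairedPair <- tr$paired[tf]
    ratio <- mean(tr$boundPairProb[pairedPair]) /
        mean(tr$boundPairProb[!pairedPair])
    expect_equal(ratio, 1 - worldParamsOf(w)@maskingStrength,
                 tolerance = 0.05)
})

test_that("expected paired-stratum effect rates are monotone in masking strength", {
    meanPairedProb <- function(strength, seed) {
        w <- generateWorld(smallWorldParams(seed = seed,
                                            maskingStrength = strength))
        tr <- worldTruth(w)
        tf <- vapply(strsplit(names(tr$boundPairProb), ":", fixed = TRUE),
                     `[[`, character(1), 1L)
        mean(tr$boundPairProb[tr$paired[tf]])
    }
    strengths <- c(0, 0.4, 0.8)
    avg <- vapply(strengths, function(s)
        mean(vapply(1:10, function(seed) meanPairedProb(s, seed),
                    numeric(1))), numeric(1))
    expect_true(all(diff(avg) < 0))
})

test_that("paralog-paired TFs receive higher computed redundancy", {
    frac <- vapply(c(6L, 7L, 8L), function(seed) {
        w <- generateWorld(worldParams(seed = seed))
        scores <- scoreAllRedundancy(w@annotationCatalog,
            names(worldTruth(w)$paired))
        fr <- frByTf(scores)
        paired <- worldTruth(w)$paired[names(fr)]
        cmp <- outer(fr[paired], fr[!paired], `>`)
        mean(cmp)
    }, numeric(1))
    expect_true(all(frac >= 0.99))
})

test_that("null-world parameters give a flat effect probability", {
    w <- generateWorld(nullCalibParams(seed = 10L))
    expect_identical(length(unique(worldTruth(w)$boundPairProb)), 1L)
})

test_that("structurally impossible probability parameters error before sampling", {
    expect_error(generateWorld(smallWorldParams(seed = 1L,
        baseEffectProb = 0.95,
        geneClassEffectMultipliers = c(tata_containing = 3,
            nfr_containing = 1, ribosomal = 1),
        classFractions = c(tata_containing = 0.5, nfr_containing = 0.5,
            ribosomal = 0.05, chromatin_remodelling = 0.1))),
        "outside \\[0,1\\]")
})

test_that("written worlds round-trip through the manifest and the pipeline", {
    world <- generateWorld(smallWorldParams(seed = 14L))
    dir <- withr::local_tempdir()
    manifest <- writeWorld(world, dir)
    expect_true(file.exists(file.path(dir, "binding.tsv")))
    expect_true(file.exists(file.path(dir, "annotations.tsv")))
    expect_identical(manifest$params$seed, 14L)
    expect_identical(manifest$realizedBaseEffectProb,
                     worldTruth(world)$base)

    # manifest regenerates the identical world
    again <- regenerateWorld(dir)
    expect_identical(records(again@bindingTable),
                     records(world@bindingTable))
    expect_identical(worldTruth(again), worldTruth(world))

    # emitted files parse back into the same significant sets
    b <- thresholdSignificant(readInteractionTable(
        file.path(dir, "binding.tsv"), "binding"), 0.005)
    expect_identical(byRegulator(b), byRegulator(
        thresholdSignificant(world@bindingTable, 0.005)))
    catalog <- readAnnotationCatalog(file.path(dir, "annotations.tsv"))
    expect_identical(termsByEntity(catalog),
                     termsByEntity(world@annotationCatalog))
})

test_that("non-significant recorded rows stay above the threshold", {
    w <- generateWorld(smallWorldParams(seed = 33L))
    p <- records(w@bindingTable)$pvalue
    alpha <- worldParamsOf(w)@alpha
    expect_true(all(p < alpha | p >= worldParamsOf(w)@nonsigPFloor))
    expect_true(any(p >= alpha))  # some recorded rows are non-significant
})
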