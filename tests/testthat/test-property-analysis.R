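# Stratified numeric and categorical comparisons, and the full-study
# orchestration.

test_that("numeric analysis builds one row pair per X with floor-sized strata", {
    withr::local_seed(3)
    genes <- sprintf("g%02d", 1:20)
    b <- mapFromList(list(t1 = genes[1:12], t2 = genes[8:20]), "binding")
    k <- mapFromList(list(t1 = genes[1:4], t2 = genes[15:20]), "knockout")
    u <- intersectUniverse(b, k)
    scores <- stats::setNames(seq_along(genes), genes)
    spec <- propertySpec("toy", "gene", "numeric_top_bottom",
                         xGrid = c(10, 20))
    res <- analyzeNumeric(spec, scores, b, k, u)
    rows <- resultRows(res)
    expect_identical(nrow(rows), 4L)
    expect_identical(rows$n_entities[rows$X == 10], c(2L, 2L))
    expect_identical(rows$n_entities[rows$X == 20], c(4L, 4L))
    expect_identical(rows$side, rep(c("top", "bottom"), 2))

    # each row reproduces the direct pooled computation on its stratum
    top10 <- stratifyTopBottom(scores, 10, "top")
    direct <- opForGeneSet(top10, b, k)
    expect_identical(rows$numerator[1], opNumerator(direct))
    expect_identical(rows$denominator[1], opDenominator(direct))

    expect_error(analyzeNumeric(spec, stats::setNames(rep(1, 20), genes),
                                b, k, u), "identical")
    expect_error(analyzeNumeric(spec,
        stats::setNames(1:3, c("zz1", "zz2", "zz3")), b, k, u),
        "no scored entities")
})

test_that("TF-level numeric analysis uses TF-set pooling", {
    withr::local_seed(9)
    b <- randomMap(10, 20, 0.4, "binding")
    k <- randomMap(10, 20, 0.4, "knockout")
    u <- intersectUniverse(b, k)
    scores <- stats::setNames(seq_along(universeTfs(u)), universeTfs(u))
    spec <- propertySpec("tf_prop", "tf", "numeric_top_bottom", xGrid = 50)
    res <- analyzeNumeric(spec, scores, b, k, u)
    rows <- resultRows(res)
    direct <- opForTfSet(stratifyTopBottom(scores, 50, "top"), b, k)
    expect_identical(rows$numerator[1], opNumerator(direct))
    expect_identical(rows$denominator[1], opDenominator(direct))
})

test_that("categorical analysis compares lists or class-vs-rest", {
    genes <- sprintf("g%02d", 1:12)
    b <- mapFromList(list(t1 = genes[1:8], t2 = genes[5:12]), "binding")
    k <- mapFromList(list(t1 = genes[1:2], t2 = genes[11:12]), "knockout")
    u <- intersectUniverse(b, k)
    two <- propertySpec("two", "gene", "categorical_two_lists")
    res <- analyzeCategorical(two, genes[1:6], genes[7:12], b, k, u)
    rows <- resultRows(res)
    expect_identical(nrow(rows), 2L)
    expect_identical(rows$side, c("list_a", "list_b"))
    expect_identical(rows$numerator[1],
        opNumerator(opForGeneSet(genes[1:6], b, k)))

    # same list on both sides: equal proportions, z = 0
    degen <- analyzeCategorical(two, genes[1:6], genes[1:6], b, k, u)
    expect_identical(resultRows(degen)$z[1], 0)
    expect_identical(resultRows(degen)$p_value[1], 0.5)

    rest <- propertySpec("rest", "gene", "categorical_vs_rest")
    resRest <- analyzeCategorical(rest, genes[1:3], NULL, b, k, u)
    expect_identical(resultRows(resRest)$side, c("class", "rest"))
    expect_identical(resultRows(resRest)$n_entities[2],
                     length(universeGenes(u)) - 3L)
    expect_error(analyzeCategorical(rest, universeGenes(u), NULL, b, k, u),
                 "empty complement")
    expect_error(analyzeCategorical(two, "not_here", genes[7:8], b, k, u),
                 "empty after universe restriction")

    # out-of-universe entries are dropped and logged
    resDrop <- analyzeCategorical(two, c(genes[1:6], "zz9"), genes[7:12],
                                  b, k, u)
    expect_identical(excludedEntities(resDrop)$entity, "zz9")
})

test_that("full study runs from written files and is deterministic", {
    world <- generateWorld(smallWorldParams(seed = 77L))
    dir <- withr::local_tempdir()
    writeWorld(world, dir)
    out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
    res1 <- runFullStudy(file.path(dir, "study.yaml"), outDir = out1)
    res2 <- runFullStudy(file.path(dir, "study.yaml"), outDir = out2)
    expect_identical(readLines(file.path(out1, "results.tsv")),
                     readLines(file.path(out2, "results.tsv")))
    expect_true(file.exists(file.path(out1, "summary.txt")))
    expect_true(file.exists(file.path(out1, "per_entity_gene.tsv")))
    expect_true(file.exists(file.path(out1, "manifest.yaml")))

    # file-based study reproduces the in-memory analysis exactly
    inMem <- analyzeWorld(world)
    expect_identical(names(res1), names(inMem))
    expect_equal(resultsTable(res1), resultsTable(inMem),
                 tolerance = 1e-12)

    # per-entity table dimensions match the universe
    u <- attr(res1, "universe")
    perGene <- utils::read.table(file.path(out1, "per_entity_gene.tsv"),
                                 header = TRUE, sep = "\t")
    expect_identical(nrow(perGene), length(universeGenes(u)))

    bad <- yaml::read_yaml(file.path(dir, "study.yaml"))
    bad$properties[[2]]$file <- "no_such_file.tsv"
    expect_error(runFullStudy(bad, baseDir = dir), "property 'expression'")
})

test_that("gene- and TF-level pooling agree on the full universe of a study", {
    world <- generateWorld(smallWorldParams(seed = 5L))
    res <- analyzeWorld(world, xGrid = 50)
    u <- attr(res, "universe")
    b <- attr(res, "binding"); k <- attr(res, "knockout")
    rt <- opForTfSet(universeTfs(u), b, k)
    rg <- opForGeneSet(universeGenes(u), b, k)
    expect_identical(opNumerator(rt), opNumerator(rg))
    expect_identical(opDenominator(rt), opDenominator(rg))
})
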