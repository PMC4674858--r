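# Shared fixture builders and independent oracles.

# Build a SignificantSetMap from a named list regulator -> gene vector.
mapFromList <- function(sets, kind = "binding", alpha = 0.005) {
    tf <- as.character(rep(names(sets), lengths(sets)))
    gene <- as.character(unlist(sets, use.names = FALSE))
    tab <- interactionTable(
        data.frame(tf = tf, gene = gene, pvalue = rep(alpha / 10, length(tf)),
                   stringsAsFactors = FALSE), kind)
    thresholdSignificant(tab, alpha)
}

# Random sparse binding/knockout map over nTf regulators and nGene genes.
randomMap <- function(nTf, nGene, density = 0.2, kind = "binding") {
    tfs <- sprintf("t%02d", seq_len(nTf))
    genes <- sprintf("g%02d", seq_len(nGene))
    sets <- lapply(tfs, function(t) genes[runif(nGene) < density])
    names(sets) <- tfs
    mapFromList(sets[lengths(sets) > 0], kind)
}

# Random interaction table with p-values spread over [0, 1].
randomTable <- function(nTf = 6, nGene = 15, kind = "binding") {
    tfs <- sprintf("t%02d", seq_len(nTf))
    genes <- sprintf("g%02d", seq_len(nGene))
    grid <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < 0.5
    grid <- grid[keep, ]
    grid$pvalue <- runif(nrow(grid))
    interactionTable(grid, kind)
}

# Desk-scale world parameters (same shape as the full-scale defaults).
smallWorldParams <- function(seed, ...) {
    worldParams(nTfs = 24L, nGenes = 300L, meanTargetsPerTf = 20,
        targetOverallOp = 0.06, backgroundEffectProb = 0.01,
        nTerms = 120L, termsPerTf = 6L, seed = seed, ...)
}

# Reduced-scale null world for test-calibration replicates: counts stay
# large enough for the normal approximation while replicates stay cheap.
nullCalibParams <- function(seed) {
    nullWorldParams(nTfs = 60L, nGenes = 900L, meanTargetsPerTf = 40,
        targetOverallOp = 0.08, backgroundEffectProb = 0.01,
        nTerms = 200L, termsPerTf = 6L, seed = seed)
}

# Independent functional-redundancy oracle: exhaustive pairwise Jaccard via
# a term-incidence matrix (a different computational route than the
# set-membership implementation).
oracleFR <- function(termsList) {
    allTerms <- sort(unique(unlist(termsList)))
    M <- vapply(termsList, function(s) allTerms %in% s,
                logical(length(allTerms)))
    M <- matrix(M, nrow = length(allTerms))
    inter <- crossprod(M)
    sz <- colSums(M)
    J <- inter / (outer(sz, sz, `+`) - inter)
    diag(J) <- -1
    fr <- apply(J, 1, max)
    partner <- vapply(seq_along(fr), function(i) {
        cand <- names(termsList)[J[i, ] == fr[i]]
        min(cand)
    }, character(1))
    list(fr = stats::setNames(fr, names(termsList)),
         partner = stats::setNames(partner, names(termsList)))
}

# Independent normal-tail oracle for one-sided proportion-test p-values.
oracleTailP <- function(z, lower) {
    if (lower) stats::integrate(stats::dnorm, -Inf, z,
                                rel.tol = 1e-13)$value
    else stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-13)$value
}

# Distinct (t, g) pair keys of a significant-set map, for brute-force
# overlap counting.
pairKeys <- function(map) {
    m <- byRegulator(map)
    if (!length(m)) return(character())
    paste(rep(names(m), lengths(m)), unlist(m, use.names = FALSE))
}
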