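# Seeded generator of complete synthetic study inputs. The generative model
# encodes the masking hypothesis: paralog-paired TFs (which share most of
# their annotation terms, hence receive high functional-redundancy scores)
# have their knockout effects on bound targets depressed by a single
# multiplicative masking parameter.

#' Construct WorldParams
#'
#' Defaults emulate the real study conditions: 173 TFs, 4065 genes, a mean
#' of 65.75 bound genes per TF (11374/173), an overall overlap percentage
#' centred at 4%, a background (indirect) knockout-effect rate sized so the
#' knockout dataset is slightly larger than the binding dataset
#' (~11,986 vs ~11,374 pairs), half of the TFs placed in high-redundancy
#' paralog pairs, and masking strength 0.8.
#'
#' @param nTfs,nGenes universe sizes.
#' @param meanTargetsPerTf Poisson mean of per-TF bound-gene counts.
#' @param baseEffectProb per-bound-pair effect probability before
#'   multipliers; the default `NA` requests deterministic normalisation so
#'   that the expected overall overlap equals `targetOverallOp`.
#' @param targetOverallOp target overall overlap fraction.
#' @param backgroundEffectProb indirect-effect probability for unbound
#'   pairs.
#' @param maskingStrength in \[0, 1\]; 0 is the null world.
#' @param paralogFraction fraction of TFs placed into pairs.
#' @param nTerms,termsPerTf,termShareRate annotation model.
#' @param geneClassEffectMultipliers,tfClassEffectMultipliers,classFractions
#'   categorical class model (names `tata_containing`, `nfr_containing`,
#'   `ribosomal`, `chromatin_remodelling`).
#' @param numericPropertyCoupling log-odds slopes per numeric property; a
#'   slope b multiplies the effect probability by `2*plogis(b*z)` where z
#'   is the gene's standardized property score (mean multiplier 1).
#' @param alpha,significantPScale,nonsigPFloor,nonsigFraction p-value
#'   emission model.
#' @param seed integer seed driving all sampling.
#' @return a [WorldParams-class].
#' @export
worldParams <- function(nTfs = 173L, nGenes = 4065L,
        meanTargetsPerTf = 65.75,
        baseEffectProb = NA_real_, targetOverallOp = 0.04,
        backgroundEffectProb = 0.0167, maskingStrength = 0.8,
        paralogFraction = 0.5, nTerms = 500L, termsPerTf = 8L,
        termShareRate = 0.75,
        geneClassEffectMultipliers = c(tata_containing = 1.8,
            nfr_containing = 0.6, ribosomal = 2.5),
        tfClassEffectMultipliers = c(chromatin_remodelling = 2.0),
        classFractions = c(tata_containing = 0.2, nfr_containing = 0.5,
            ribosomal = 0.05, chromatin_remodelling = 0.1),
        numericPropertyCoupling = c(expression = 0.4,
            transcriptional_plasticity = 0.4, n_bound_tfs = 0.4,
            n_tfbs = 0.4, mean_tfbs_tss_distance = 0.4),
        alpha = 0.005, significantPScale = 1, nonsigPFloor = 0.05,
        nonsigFraction = 0.1, seed = 1L) {
    new("WorldParams", nTfs = as.integer(nTfs), nGenes = as.integer(nGenes),
        meanTargetsPerTf = meanTargetsPerTf,
        baseEffectProb = baseEffectProb, targetOverallOp = targetOverallOp,
        backgroundEffectProb = backgroundEffectProb,
        maskingStrength = maskingStrength,
        paralogFraction = paralogFraction, nTerms = as.integer(nTerms),
        termsPerTf = as.integer(termsPerTf), termShareRate = termShareRate,
        geneClassEffectMultipliers = geneClassEffectMultipliers,
        tfClassEffectMultipliers = tfClassEffectMultipliers,
        classFractions = classFractions,
        numericPropertyCoupling = numericPropertyCoupling,
        alpha = alpha, significantPScale = significantPScale,
        nonsigPFloor = nonsigPFloor, nonsigFraction = nonsigFraction,
        seed = as.integer(seed))
}

#' Null-world parameters
#'
#' [worldParams()] with no masking, unit class multipliers and zero numeric
#' couplings: every bound pair has the same effect probability, so stratum
#' overlap percentages differ only by sampling noise and one-sided
#' proportion-test p-values are Uniform(0, 1).
#'
#' @param ... overrides passed on to [worldParams()].
#' @return a [WorldParams-class].
#' @export
nullWorldParams <- function(...) {
    args <- list(...)
    base <- list(maskingStrength = 0,
        geneClassEffectMultipliers = c(tata_containing = 1,
            nfr_containing = 1, ribosomal = 1),
        tfClassEffectMultipliers = c(chromatin_remodelling = 1),
        numericPropertyCoupling = c(expression = 0,
            transcriptional_plasticity = 0, n_bound_tfs = 0,
            n_tfbs = 0, mean_tfbs_tss_distance = 0))
    do.call(worldParams, utils::modifyList(base, args))
}

.standardize <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# sample `n` (tf, gene) pairs avoiding keys in `exclude` (and each other)
.samplePairsOutside <- function(tfIds, geneIds, n, exclude) {
    out <- character(0)
    tries <- 0L
    while (length(out) < n && tries < 50L) {
        t <- sample(tfIds, n, replace = TRUE)
        g <- sample(geneIds, n, replace = TRUE)
        key <- paste(t, g, sep = "\r")
        key <- key[!(key %in% exclude) & !(key %in% out)]
        out <- c(out, unique(key))
        tries <- tries + 1L
    }
    out <- utils::head(out, n)
    parts <- strsplit(out, "\r", fixed = TRUE)
    list(tf = vapply(parts, `[[`, character(1), 1L),
         gene = vapply(parts, `[[`, character(1), 2L))
}

#' Generate a complete synthetic regulatory world
#'
#' The generative model, all driven by `seed`:
#' \enumerate{
#'   \item a `paralogFraction` of TFs is placed into pairs whose members
#'     share a core of annotation terms (true high redundancy); the
#'     remaining TFs draw near-disjoint term sets from a large pool;
#'   \item each TF binds a Poisson-sized random gene set;
#'   \item each bound pair (t, g) shows a knockout effect with probability
#'     `base * (1 - maskingStrength * paired(t)) * classMultipliers *
#'     logistic numeric-property adjustments`, clipped to \[0, 1\];
#'     unbound pairs show indirect effects at `backgroundEffectProb`;
#'   \item significant pairs receive p-values Uniform(0,
#'     `significantPScale * alpha`); each table also records a fraction of
#'     non-significant rows with p-values above `nonsigPFloor`;
#'   \item gene classes and numeric property tables are emitted with the
#'     stated couplings.
#' }
#' When `baseEffectProb` is `NA`, the base rate is set deterministically so
#' that the expected overall overlap over the realized bound pairs equals
#' `targetOverallOp`; the realized base is recorded in the world's truth.
#' An error is raised before sampling if more than 5% of bound pairs would
#' need clipping.
#'
#' @param params a [WorldParams-class].
#' @return a [SyntheticWorld-class].
#' @seealso [writeWorld()], [analyzeWorld()]
#' @export
generateWorld <- function(params) {
    stopifnot(is(params, "WorldParams"))
    p <- params
    set.seed(p@seed)
    n <- p@nTfs; m <- p@nGenes
    tfs <- sprintf("TF%03d", seq_len(n))
    genes <- sprintf("YG%05d", seq_len(m))
    termPool <- sprintf("T%04d", seq_len(p@nTerms))

    ## 1. pairing and annotation terms
    nPair <- 2L * floor(p@paralogFraction * n / 2)
    pairedIdx <- if (nPair > 0L) sample(n, nPair) else integer()
    paired <- stats::setNames(rep(FALSE, n), tfs)
    paired[pairedIdx] <- TRUE
    partnerTf <- stats::setNames(rep(NA_character_, n), tfs)
    terms <- vector("list", n)
    names(terms) <- tfs
    kCore <- max(1L, round(p@termShareRate * p@termsPerTf))
    kPriv <- p@termsPerTf - kCore
    if (nPair > 0L) {
        pairMat <- matrix(pairedIdx, ncol = 2L)
        for (r in seq_len(nrow(pairMat))) {
            i <- pairMat[r, 1L]; j <- pairMat[r, 2L]
            partnerTf[i] <- tfs[j]; partnerTf[j] <- tfs[i]
            core <- sample(termPool, kCore)
            rest <- setdiff(termPool, core)
            terms[[i]] <- c(core, sample(rest, kPriv))
            terms[[j]] <- c(core, sample(rest, kPriv))
        }
    }
    for (i in which(!paired))
        terms[[i]] <- sample(termPool, p@termsPerTf)
    catalog <- annotationCatalog(terms, "synthetic")

    ## 2. binding
    nTargets <- pmax(1L, stats::rpois(n, p@meanTargetsPerTf))
    boundGenes <- lapply(nTargets, function(k) sort(sample(genes, k)))
    names(boundGenes) <- tfs
    pairTf <- rep(tfs, lengths(boundGenes))
    pairGene <- unlist(boundGenes, use.names = FALSE)
    nPairs <- length(pairTf)

    ## 3. classes and numeric properties
    fr <- p@classFractions
    tata <- stats::runif(m) < fr[["tata_containing"]]
    nfr <- stats::runif(m) < fr[["nfr_containing"]]
    ribo <- stats::runif(m) < fr[["ribosomal"]]
    chrom <- stats::runif(n) < fr[["chromatin_remodelling"]]
    nBound <- stats::setNames(integer(m), genes)
    tab <- table(pairGene)
    nBound[names(tab)] <- as.integer(tab)
    exprLatent <- stats::rnorm(m)
    plasticity <- stats::rnorm(m)
    nTfbs <- as.integer(nBound) + stats::rpois(m, 2)
    distTss <- exp(stats::rnorm(m, log(200), 0.5))
    propertyTables <- list(
        expression = data.frame(gene = genes, value = exp(exprLatent),
            stringsAsFactors = FALSE),
        transcriptional_plasticity = data.frame(gene = genes,
            value = plasticity, stringsAsFactors = FALSE),
        n_bound_tfs = data.frame(gene = genes, value = as.numeric(nBound),
            stringsAsFactors = FALSE),
        n_tfbs = data.frame(gene = genes, value = as.numeric(nTfbs),
            stringsAsFactors = FALSE),
        mean_tfbs_tss_distance = data.frame(gene = genes, value = distTss,
            stringsAsFactors = FALSE))

    ## 4. effect probabilities on bound pairs
    beta <- p@numericPropertyCoupling
    zmat <- cbind(expression = .standardize(exprLatent),
        transcriptional_plasticity = .standardize(plasticity),
        n_bound_tfs = .standardize(as.numeric(nBound)),
        n_tfbs = .standardize(as.numeric(nTfbs)),
        mean_tfbs_tss_distance = .standardize(log(distTss)))
    geneFactor <- rep(1, m)
    for (nm in colnames(zmat)) {
        b <- if (nm %in% names(beta)) beta[[nm]] else 0
        if (b != 0) geneFactor <- geneFactor * 2 * stats::plogis(b * zmat[, nm])
    }
    gm <- p@geneClassEffectMultipliers
    geneFactor <- geneFactor * ifelse(tata, gm[["tata_containing"]], 1) *
        ifelse(nfr, gm[["nfr_containing"]], 1) *
        ifelse(ribo, gm[["ribosomal"]], 1)
    names(geneFactor) <- genes
    tfFactor <- (1 - p@maskingStrength * paired) *
        ifelse(chrom, p@tfClassEffectMultipliers[["chromatin_remodelling"]], 1)
    names(tfFactor) <- tfs
    pairFactor <- tfFactor[pairTf] * geneFactor[pairGene]
    base <- p@baseEffectProb
    if (is.na(base)) {
        base <- p@targetOverallOp * nPairs / sum(pairFactor)
        if (base > 1)
            stop("normalisation requires base effect probability > 1; ",
                 "lower targetOverallOp or raise the multipliers")
    }
    probs <- base * pairFactor
    if (mean(probs > 1) > 0.05)
        stop("parameters force effect probabilities outside [0,1] for >5% ",
             "of bound pairs")
    probs <- pmin(probs, 1)
    directEffect <- stats::runif(nPairs) < probs

    ## 5. background (indirect) knockout effects on unbound pairs
    koTf <- pairTf[directEffect]
    koGene <- pairGene[directEffect]
    if (p@backgroundEffectProb > 0) {
        for (i in seq_len(n)) {
            unbound <- setdiff(genes, boundGenes[[i]])
            nbg <- stats::rbinom(1L, length(unbound), p@backgroundEffectProb)
            if (nbg > 0L) {
                koTf <- c(koTf, rep(tfs[i], nbg))
                koGene <- c(koGene, sample(unbound, nbg))
            }
        }
    }

    ## 6. p-values and recorded non-significant rows
    sigUpper <- p@significantPScale * p@alpha
    nonsigLow <- max(p@nonsigPFloor, p@alpha)
    mkTable <- function(sigTf, sigGene, kind) {
        nSig <- length(sigTf)
        pv <- stats::runif(nSig, 0, sigUpper)
        sigKey <- paste(sigTf, sigGene, sep = "\r")
        nExtra <- round(p@nonsigFraction * nSig)
        if (nExtra > 0L) {
            extra <- .samplePairsOutside(tfs, genes, nExtra, sigKey)
            sigTf <- c(sigTf, extra$tf)
            sigGene <- c(sigGene, extra$gene)
            pv <- c(pv, stats::runif(length(extra$tf), nonsigLow, 1))
        }
        interactionTable(data.frame(tf = sigTf, gene = sigGene,
            pvalue = pv, stringsAsFactors = FALSE), kind)
    }
    bindingTable <- mkTable(pairTf, pairGene, "binding")
    knockoutTable <- mkTable(koTf, koGene, "knockout")

    truth <- list(
        base = base, background = p@backgroundEffectProb,
        tfFactor = tfFactor, geneFactor = geneFactor,
        paired = paired, partnerTf = partnerTf,
        chromatinRemodelling = stats::setNames(chrom, tfs),
        geneClasses = list(
            tata_containing = stats::setNames(tata, genes),
            nfr_containing = stats::setNames(nfr, genes),
            ribosomal = stats::setNames(ribo, genes)),
        boundPairProb = stats::setNames(probs,
            paste(pairTf, pairGene, sep = ":")))
    classLists <- list(
        tata_containing = genes[tata], tata_less = genes[!tata],
        nfr_containing = genes[nfr], nfr_lacking = genes[!nfr],
        ribosomal = genes[ribo], chromatin_remodelling = tfs[chrom])
    new("SyntheticWorld", bindingTable = bindingTable,
        knockoutTable = knockoutTable, annotationCatalog = catalog,
        propertyTables = propertyTables, classLists = classLists,
        truth = truth, params = p)
}

.defaultPanels <- function(xGrid = c(10, 20, 30, 40, 50)) {
    list(
        list(name = "functional_redundancy", level = "tf",
            mode = "numeric_top_bottom", source = "annotations",
            direction = "first_group_lower", x_grid = xGrid),
        list(name = "expression", level = "gene",
            mode = "numeric_top_bottom", source = "expression",
            direction = "first_group_higher", x_grid = xGrid),
        list(name = "transcriptional_plasticity", level = "gene",
            mode = "numeric_top_bottom",
            source = "transcriptional_plasticity",
            direction = "first_group_higher", x_grid = xGrid),
        list(name = "n_bound_tfs", level = "gene",
            mode = "numeric_top_bottom", source = "n_bound_tfs",
            direction = "first_group_higher", x_grid = xGrid),
        list(name = "n_tfbs", level = "gene", mode = "numeric_top_bottom",
            source = "n_tfbs", direction = "first_group_higher",
            x_grid = xGrid),
        list(name = "mean_tfbs_tss_distance", level = "gene",
            mode = "numeric_top_bottom", source = "mean_tfbs_tss_distance",
            direction = "first_group_higher", x_grid = xGrid),
        list(name = "tata_box", level = "gene",
            mode = "categorical_two_lists", list_a = "tata_less",
            list_b = "tata_containing", direction = "first_group_lower"),
        list(name = "nfr", level = "gene", mode = "categorical_two_lists",
            list_a = "nfr_containing", list_b = "nfr_lacking",
            direction = "first_group_lower"),
        list(name = "ribosomal", level = "gene",
            mode = "categorical_vs_rest", list_a = "ribosomal",
            direction = "first_group_higher"),
        list(name = "chromatin_remodelling", level = "tf",
            mode = "categorical_vs_rest", list_a = "chromatin_remodelling",
            direction = "first_group_higher"))
}

#' Run the full panel of stratified comparisons on a synthetic world
#'
#' In-memory equivalent of writing the world to disk and running
#' [runFullStudy()] on the emitted files: thresholds both tables at the
#' world's alpha, builds the universe, and runs the standard panels —
#' functional redundancy (TF level, scores computed from the world's
#' annotation catalog), the five numeric gene properties, TATA-box and NFR
#' two-list comparisons, ribosomal genes vs rest, and chromatin-remodelling
#' TFs vs rest.
#'
#' @param world a [SyntheticWorld-class].
#' @param xGrid X percentages for the numeric panels.
#' @return named list of [AnalysisResult-class] objects with attributes
#'   `universe`, `binding`, `knockout`.
#' @export
analyzeWorld <- function(world, xGrid = c(10, 20, 30, 40, 50)) {
    stopifnot(is(world, "SyntheticWorld"))
    alpha <- world@params@alpha
    binding <- thresholdSignificant(world@bindingTable, alpha)
    knockout <- thresholdSignificant(world@knockoutTable, alpha)
    universe <- intersectUniverse(binding, knockout)
    binding <- restrictToUniverse(binding, universe)
    knockout <- restrictToUniverse(knockout, universe)
    propScore <- function(nm) {
        d <- world@propertyTables[[nm]]
        stats::setNames(d$value, d$gene)
    }
    results <- list()
    for (panel in .defaultPanels(xGrid)) {
        res <- if (panel$mode == "numeric_top_bottom") {
            scores <- if (panel$source == "annotations")
                frByTf(scoreAllRedundancy(world@annotationCatalog,
                                          universeTfs(universe)))
            else propScore(panel$source)
            src <- if (panel$source == "annotations")
                sourceLabel(world@annotationCatalog) else NA_character_
            analyzeNumeric(
                propertySpec(panel$name, panel$level, panel$mode,
                    panel$x_grid, panel$direction, src),
                scores, binding, knockout, universe)
        } else {
            analyzeCategorical(
                propertySpec(panel$name, panel$level, panel$mode,
                    expectedDirection = panel$direction),
                world@classLists[[panel$list_a]],
                if (panel$mode == "categorical_two_lists")
                    world@classLists[[panel$list_b]] else NULL,
                binding, knockout, universe)
        }
        results[[panel$name]] <- res
    }
    attr(results, "universe") <- universe
    attr(results, "binding") <- binding
    attr(results, "knockout") <- knockout
    results
}

.paramsToList <- function(p) {
    list(nTfs = p@nTfs, nGenes = p@nGenes,
        meanTargetsPerTf = p@meanTargetsPerTf,
        baseEffectProb = p@baseEffectProb,
        targetOverallOp = p@targetOverallOp,
        backgroundEffectProb = p@backgroundEffectProb,
        maskingStrength = p@maskingStrength,
        paralogFraction = p@paralogFraction, nTerms = p@nTerms,
        termsPerTf = p@termsPerTf, termShareRate = p@termShareRate,
        geneClassEffectMultipliers = as.list(p@geneClassEffectMultipliers),
        tfClassEffectMultipliers = as.list(p@tfClassEffectMultipliers),
        classFractions = as.list(p@classFractions),
        numericPropertyCoupling = as.list(p@numericPropertyCoupling),
        alpha = p@alpha, significantPScale = p@significantPScale,
        nonsigPFloor = p@nonsigPFloor, nonsigFraction = p@nonsigFraction,
        seed = p@seed)
}

# Build WorldParams from a (possibly partial) plain list, e.g. a parsed
# manifest or a user params.yaml; fields not named fall back to defaults.
.paramsFromList <- function(x) {
    vecFields <- c("geneClassEffectMultipliers", "tfClassEffectMultipliers",
                   "classFractions", "numericPropertyCoupling")
    known <- names(formals(worldParams))
    args <- x[intersect(names(x), known)]
    args <- args[!vapply(args, is.null, logical(1))]
    for (f in intersect(vecFields, names(args)))
        args[[f]] <- unlist(args[[f]])
    if (!is.null(args$baseEffectProb))
        args$baseEffectProb <- as.numeric(args$baseEffectProb)
    do.call(worldParams, args)
}

#' Write a synthetic world to a directory of flat files
#'
#' Emits every file the pipeline consumes — `binding.tsv`, `knockout.tsv`,
#' `annotations.tsv`, one `<property>.tsv` per numeric property, one
#' `<class>.txt` per class list — plus ground-truth sidecars
#' (`truth_tf.tsv`, `truth_gene.tsv`), a `manifest.yaml` recording the
#' parameters and seed (sufficient to regenerate the identical world via
#' [regenerateWorld()]), and a ready-to-run `study.yaml` configuration for
#' [runFullStudy()].
#'
#' @param world a [SyntheticWorld-class].
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
writeWorld <- function(world, directory) {
    stopifnot(is(world, "SyntheticWorld"))
    dir.create(directory, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(directory))
        stop("cannot create directory ", directory)
    fp <- function(...) file.path(directory, ...)
    writeInteractionTable(world@bindingTable, fp("binding.tsv"))
    writeInteractionTable(world@knockoutTable, fp("knockout.tsv"))
    tbe <- termsByEntity(world@annotationCatalog)
    writeLines(paste(rep(names(tbe), lengths(tbe)),
        unlist(tbe, use.names = FALSE), sep = "\t"), fp("annotations.tsv"))
    for (nm in names(world@propertyTables)) {
        d <- world@propertyTables[[nm]]
        d$value <- sprintf("%.17g", d$value)
        utils::write.table(d, fp(paste0(nm, ".tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    for (nm in names(world@classLists))
        writeLines(world@classLists[[nm]], fp(paste0(nm, ".txt")))
    tr <- world@truth
    utils::write.table(data.frame(tf = names(tr$tfFactor),
        paired = unname(tr$paired), partner = unname(tr$partnerTf),
        chromatin_remodelling = unname(tr$chromatinRemodelling),
        effect_factor = sprintf("%.17g", unname(tr$tfFactor)),
        stringsAsFactors = FALSE), fp("truth_tf.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = names(tr$geneFactor),
        tata_containing = unname(tr$geneClasses$tata_containing),
        nfr_containing = unname(tr$geneClasses$nfr_containing),
        ribosomal = unname(tr$geneClasses$ribosomal),
        effect_factor = sprintf("%.17g", unname(tr$geneFactor)),
        stringsAsFactors = FALSE), fp("truth_gene.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    panels <- lapply(.defaultPanels(), function(pl) {
        out <- list(name = pl$name, level = pl$level, mode = pl$mode,
                    direction = pl$direction)
        if (pl$mode == "numeric_top_bottom") {
            out$x_grid <- pl$x_grid
            if (pl$source == "annotations") {
                out$annotations <- "annotations.tsv"
                out$annotation_label <- sourceLabel(world@annotationCatalog)
            } else out$file <- paste0(pl$source, ".tsv")
        } else {
            out$list_a <- paste0(pl$list_a, ".txt")
            if (pl$mode == "categorical_two_lists")
                out$list_b <- paste0(pl$list_b, ".txt")
        }
        out
    })
    study <- list(binding = "binding.tsv", knockout = "knockout.tsv",
        alpha = world@params@alpha, properties = panels)
    yaml::write_yaml(study, fp("study.yaml"))
    dataFiles <- setdiff(list.files(directory),
                         c("manifest.yaml", "study.yaml"))
    manifest <- list(
        generator = "TFKOverlap::generateWorld",
        params = .paramsToList(world@params),
        realizedBaseEffectProb = tr$base,
        files = as.list(tools::md5sum(fp(dataFiles))))
    names(manifest$files) <- dataFiles
    yaml::write_yaml(manifest, fp("manifest.yaml"))
    invisible(manifest)
}

#' Regenerate a world from a written manifest
#'
#' Reads `manifest.yaml` from a directory written by [writeWorld()] and
#' re-runs [generateWorld()] with the recorded parameters and seed,
#' reproducing the identical world.
#'
#' @param directory a directory containing `manifest.yaml` (or a direct
#'   path to a manifest file).
#' @return a [SyntheticWorld-class].
#' @export
regenerateWorld <- function(directory) {
    path <- if (dir.exists(directory))
        file.path(directory, "manifest.yaml") else directory
    if (!file.exists(path))
        stop("missing manifest: ", path)
    manifest <- yaml::read_yaml(path)
    generateWorld(.paramsFromList(manifest$params))
}
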