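# Generic stratified overlap-percentage pipeline over TF and gene
# properties: numeric top/bottom-X% strata and categorical class lists.

#' Construct a PropertySpec
#'
#' @param name comparison name (appears in the results table).
#' @param level `"tf"` or `"gene"`: which side of the interaction the
#'   property describes, hence whether TF-set or gene-set pooling is used.
#' @param mode `"numeric_top_bottom"`, `"categorical_two_lists"` or
#'   `"categorical_vs_rest"`.
#' @param xGrid X percentages for numeric mode, each in (0, 50\].
#' @param expectedDirection `"first_group_lower"`, `"first_group_higher"`
#'   or `"none"`; the first group is the top stratum (numeric mode) or
#'   list A (categorical modes). Determines the one-sided alternative;
#'   `"none"` tests `first_group_lower` by convention.
#' @param annotationSource optional label of the annotation catalog behind
#'   the scores.
#' @return a [PropertySpec-class].
#' @export
propertySpec <- function(name, level, mode,
                         xGrid = c(10, 20, 30, 40, 50),
                         expectedDirection = "none",
                         annotationSource = NA_character_) {
    new("PropertySpec", name = name, level = level, mode = mode,
        xGrid = as.numeric(xGrid), expectedDirection = expectedDirection,
        annotationSource = annotationSource)
}

.alternativeFor <- function(direction) {
    if (direction == "first_group_higher") "group1_greater" else "group1_less"
}

.resultRowPair <- function(spec, X, sides, groups, test) {
    data.frame(
        comparison = spec@name,
        annotation_source = spec@annotationSource,
        X = X,
        side = sides,
        n_entities = vapply(groups, function(g)
            length(attr(g, "entities")), integer(1)),
        numerator = vapply(groups, opNumerator, integer(1)),
        denominator = vapply(groups, opDenominator, integer(1)),
        op = vapply(groups, opValue, numeric(1)),
        z = test@z,
        p_value = test@pValue,
        stringsAsFactors = FALSE)
}

.opForEntities <- function(entities, level, binding, knockout, label) {
    res <- if (level == "tf") opForTfSet(entities, binding, knockout, label)
           else opForGeneSet(entities, binding, knockout, label)
    attr(res, "entities") <- entities
    res
}

#' Stratified overlap comparison over a numeric property
#'
#' For each X in the spec's grid, splits the scored entities into top-X% and
#' bottom-X% strata, pools the overlap percentage of each stratum (TF-set
#' pooling for TF-level properties, gene-set pooling for gene-level ones)
#' and runs the one-sided two-sample proportion test with the alternative
#' implied by the spec's expected direction (group 1 = top stratum).
#'
#' @param spec a [PropertySpec-class] with mode `"numeric_top_bottom"`.
#' @param scores named numeric vector keyed at the spec's level.
#' @param binding,knockout [SignificantSetMap-class] objects.
#' @param universe a [StudyUniverse-class]; scores outside it are dropped
#'   and logged.
#' @return an [AnalysisResult-class].
#' @export
analyzeNumeric <- function(spec, scores, binding, knockout, universe) {
    stopifnot(is(spec, "PropertySpec"), is(universe, "StudyUniverse"))
    if (spec@mode != "numeric_top_bottom")
        stop("analyzeNumeric requires mode 'numeric_top_bottom'")
    entities <- if (spec@level == "tf") universe@tfs else universe@genes
    dropped <- setdiff(names(scores), entities)
    scores <- scores[names(scores) %in% entities]
    if (!length(scores))
        stop("no scored entities remain in the universe")
    if (length(unique(scores)) == 1L)
        stop("all scores are identical; top/bottom strata are undefined")
    exclusions <- data.frame(entity = dropped,
        reason = rep("not_in_universe", length(dropped)),
        stringsAsFactors = FALSE)
    alt <- .alternativeFor(spec@expectedDirection)
    rows <- list(); tests <- list()
    for (i in seq_along(spec@xGrid)) {
        X <- spec@xGrid[i]
        top <- stratifyTopBottom(scores, X, "top")
        bottom <- stratifyTopBottom(scores, X, "bottom")
        g1 <- .opForEntities(top, spec@level, binding, knockout,
            sprintf("%s top %g%%", spec@name, X))
        g2 <- .opForEntities(bottom, spec@level, binding, knockout,
            sprintf("%s bottom %g%%", spec@name, X))
        tests[[i]] <- proportionTest(g1, g2, alt)
        rows[[i]] <- .resultRowPair(spec, X, c("top", "bottom"),
            list(g1, g2), tests[[i]])
    }
    new("AnalysisResult", spec = spec, rows = do.call(rbind, rows),
        tests = tests, exclusions = exclusions)
}

#' Overlap comparison between two categorical entity lists
#'
#' Compares the pooled overlap percentage of list A against either a second
#' explicit list (`categorical_two_lists`) or the rest of the universe at
#' the spec's level (`categorical_vs_rest`). List entries outside the
#' universe are dropped and logged.
#'
#' @param spec a [PropertySpec-class] with a categorical mode.
#' @param listA character vector of entity ids (group 1).
#' @param listB character vector for the second group, or `NULL` /
#'   `"rest"` in vs-rest mode.
#' @inheritParams analyzeNumeric
#' @return an [AnalysisResult-class].
#' @export
analyzeCategorical <- function(spec, listA, listB = NULL, binding, knockout,
                               universe) {
    stopifnot(is(spec, "PropertySpec"), is(universe, "StudyUniverse"))
    if (!(spec@mode %in% c("categorical_two_lists", "categorical_vs_rest")))
        stop("analyzeCategorical requires a categorical mode")
    entities <- if (spec@level == "tf") universe@tfs else universe@genes
    listA <- unique(as.character(listA))
    droppedA <- setdiff(listA, entities)
    a <- sort(intersect(listA, entities))
    if (!length(a))
        stop("group 'list_a' is empty after universe restriction")
    if (spec@mode == "categorical_vs_rest") {
        b <- setdiff(entities, a)
        if (!length(b))
            stop("empty complement: list_a covers the entire universe")
        droppedB <- character()
        sides <- c("class", "rest")
    } else {
        if (is.null(listB) || identical(listB, "rest"))
            stop("mode 'categorical_two_lists' needs an explicit second list")
        listB <- unique(as.character(listB))
        droppedB <- setdiff(listB, entities)
        b <- sort(intersect(listB, entities))
        if (!length(b))
            stop("group 'list_b' is empty after universe restriction")
        sides <- c("list_a", "list_b")
    }
    exclusions <- data.frame(
        entity = c(droppedA, droppedB),
        reason = rep("not_in_universe", length(droppedA) + length(droppedB)),
        stringsAsFactors = FALSE)
    g1 <- .opForEntities(a, spec@level, binding, knockout,
        sprintf("%s %s", spec@name, sides[1]))
    g2 <- .opForEntities(b, spec@level, binding, knockout,
        sprintf("%s %s", spec@name, sides[2]))
    test <- proportionTest(g1, g2, .alternativeFor(spec@expectedDirection))
    new("AnalysisResult", spec = spec,
        rows = .resultRowPair(spec, NA_real_, sides, list(g1, g2), test),
        tests = list(test), exclusions = exclusions)
}

#' Number of TFs bound to each universe gene
#'
#' Convenience score |T_B(g)| computed directly from the binding map; the
#' one numeric gene property fully determined by data already in hand.
#'
#' @param binding a [SignificantSetMap-class] of binding calls.
#' @param universe a [StudyUniverse-class].
#' @return named numeric vector over `universeGenes(universe)` (0 for
#'   unbound genes).
#' @export
boundTfCounts <- function(binding, universe) {
    stopifnot(is(binding, "SignificantSetMap"), is(universe, "StudyUniverse"))
    counts <- stats::setNames(numeric(length(universe@genes)),
                              universe@genes)
    n <- lengths(binding@byGene)
    hit <- intersect(names(n), universe@genes)
    counts[hit] <- n[hit]
    counts
}

# join a config-relative path to the base directory, leaving absolute
# paths untouched
.resolvePath <- function(baseDir, path) {
    if (startsWith(path, "/") || grepl("^[A-Za-z]:", path)) path
    else file.path(baseDir, path)
}

.studyProperty <- function(entry, ctx) {
    name <- entry$name
    if (is.null(name)) stop("config property without a name")
    tryCatch({
        level <- entry$level
        mode <- entry$mode
        direction <- if (is.null(entry$direction)) "none" else entry$direction
        xGrid <- if (is.null(entry$x_grid)) c(10, 20, 30, 40, 50)
                 else as.numeric(unlist(entry$x_grid))
        if (mode == "numeric_top_bottom") {
            if (!is.null(entry$annotations)) {
                catalog <- readAnnotationCatalog(
                    .resolvePath(ctx$baseDir, entry$annotations),
                    if (is.null(entry$annotation_label)) entry$annotations
                    else entry$annotation_label)
                scores <- frByTf(scoreAllRedundancy(catalog,
                    universeTfs(ctx$universe)))
                src <- sourceLabel(catalog)
            } else if (!is.null(entry$derive)) {
                if (!identical(entry$derive, "n_bound_tfs"))
                    stop("unknown derived property '", entry$derive, "'")
                scores <- boundTfCounts(ctx$binding, ctx$universe)
                src <- NA_character_
            } else if (!is.null(entry$file)) {
                scores <- readPropertyTable(.resolvePath(ctx$baseDir, entry$file))
                src <- NA_character_
            } else stop("numeric property needs 'file', 'annotations' or 'derive'")
            spec <- propertySpec(name, level, mode, xGrid, direction, src)
            analyzeNumeric(spec, scores, ctx$binding, ctx$knockout,
                           ctx$universe)
        } else {
            listA <- readEntityList(.resolvePath(ctx$baseDir, entry$list_a))
            listB <- if (mode == "categorical_two_lists")
                readEntityList(.resolvePath(ctx$baseDir, entry$list_b))
            else NULL
            spec <- propertySpec(name, level, mode, c(10), direction)
            analyzeCategorical(spec, listA, listB, ctx$binding,
                               ctx$knockout, ctx$universe)
        }
    }, error = function(e)
        stop("property '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run a full stratified-overlap study from a configuration
#'
#' Reads the binding and knockout interaction tables, thresholds them,
#' builds the study universe, runs every configured property comparison
#' and (optionally) writes the results table, a plain-text summary,
#' per-entity overlap tables and a run manifest.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' top-level keys `binding`, `knockout`, `alpha` (or
#' `pre_thresholded: true`), and a list `properties` whose entries carry
#' `name`, `level`, `mode`, `direction`, and per-mode inputs: `file`
#' (two-column score TSV), `annotations` (+ optional `annotation_label`;
#' functional-redundancy scores are computed from the catalog),
#' `derive: n_bound_tfs`, or `list_a` / `list_b` files. File paths are
#' resolved relative to the configuration file.
#'
#' @param config path to a YAML study configuration, or a named list.
#' @param outDir optional output directory for `results.tsv`,
#'   `summary.txt`, `per_entity_tf.tsv`, `per_entity_gene.tsv` and
#'   `manifest.yaml`.
#' @param baseDir directory against which input paths are resolved;
#'   defaults to the configuration file's directory.
#' @return named list of [AnalysisResult-class] objects, in configuration
#'   order, with attributes `universe`, `binding`, `knockout`.
#' @export
runFullStudy <- function(config, outDir = NULL, baseDir = NULL) {
    configPath <- NULL
    if (is.character(config)) {
        configPath <- config
        if (!file.exists(configPath))
            stop("missing config file: ", configPath)
        if (is.null(baseDir)) baseDir <- dirname(configPath)
        config <- yaml::read_yaml(configPath)
    }
    if (is.null(baseDir)) baseDir <- "."
    for (key in c("binding", "knockout", "properties"))
        if (is.null(config[[key]]))
            stop("study config is missing '", key, "'")
    bindingTab <- readInteractionTable(
        .resolvePath(baseDir, config$binding), "binding")
    knockoutTab <- readInteractionTable(
        .resolvePath(baseDir, config$knockout), "knockout")
    alpha <- if (isTRUE(config$pre_thresholded)) NULL
             else if (is.null(config$alpha)) 0.005 else config$alpha
    binding <- thresholdSignificant(bindingTab, alpha)
    knockout <- thresholdSignificant(knockoutTab, alpha)
    universe <- intersectUniverse(binding, knockout)
    binding <- restrictToUniverse(binding, universe)
    knockout <- restrictToUniverse(knockout, universe)
    ctx <- list(baseDir = baseDir, binding = binding, knockout = knockout,
                universe = universe)
    results <- lapply(config$properties, .studyProperty, ctx = ctx)
    names(results) <- vapply(config$properties, `[[`, character(1), "name")
    attr(results, "universe") <- universe
    attr(results, "binding") <- binding
    attr(results, "knockout") <- knockout
    if (!is.null(outDir)) {
        renderReport(results, outDir)
        utils::write.table(
            perEntityOverlap(binding, knockout, universe, "tf"),
            file.path(outDir, "per_entity_tf.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        utils::write.table(
            perEntityOverlap(binding, knockout, universe, "gene"),
            file.path(outDir, "per_entity_gene.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        inputs <- c(.resolvePath(baseDir, config$binding),
                    .resolvePath(baseDir, config$knockout))
        writeRunManifest(outDir, "run-all", configPath, inputs)
    }
    results
}
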