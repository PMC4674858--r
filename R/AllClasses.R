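#' @import methods
NULL

.DATASET_KINDS <- c("binding", "knockout")

#' InteractionTable: raw regulator-gene interaction records
#'
#' Holds raw (tf, gene, pvalue) records for either a TF binding dataset
#' (ChIP-chip style significance calls) or a TF knockout-effect dataset
#' (differential expression upon TF deletion). Records are validated on
#' construction: p-values must lie in \[0, 1\], identifiers must be non-empty,
#' and duplicate (tf, gene) pairs are an error.
#'
#' @slot records data.frame with character columns `tf`, `gene` and numeric
#'   column `pvalue`.
#' @slot datasetKind either `"binding"` or `"knockout"`.
#'
#' @seealso [interactionTable()], [readInteractionTable()],
#'   [thresholdSignificant()]
#' @exportClass InteractionTable
setClass("InteractionTable",
    slots = c(records = "data.frame", datasetKind = "character"))

setValidity("InteractionTable", function(object) {
    msgs <- character()
    if (!(length(object@datasetKind) == 1L &&
          object@datasetKind %in% .DATASET_KINDS))
        msgs <- c(msgs, "datasetKind must be 'binding' or 'knockout'")
    rec <- object@records
    need <- c("tf", "gene", "pvalue")
    if (!all(need %in% names(rec)))
        return(c(msgs, "records must have columns tf, gene, pvalue"))
    if (!is.character(rec$tf) || !is.character(rec$gene))
        msgs <- c(msgs, "tf and gene must be character")
    if (anyNA(rec$tf) || anyNA(rec$gene) ||
        any(!nzchar(rec$tf)) || any(!nzchar(rec$gene)))
        msgs <- c(msgs, "tf and gene identifiers must be non-empty")
    if (!is.numeric(rec$pvalue) || anyNA(rec$pvalue) ||
        any(rec$pvalue < 0 | rec$pvalue > 1))
        msgs <- c(msgs, "p-value out of range [0,1]")
    if (anyDuplicated(paste(rec$tf, rec$gene, sep = "\r")))
        msgs <- c(msgs, "duplicate interaction (tf, gene) pair")
    if (length(msgs)) msgs else TRUE
})

#' SignificantSetMap: significant TF-gene calls as a two-way set map
#'
#' Stores, for one dataset thresholded at `alpha`, the map from each
#' regulator to its set of significant genes (G_B(t) or G_K(t)) together with
#' the exact transpose keyed by gene (T_B(g) or T_K(g)). The two maps are
#' required to encode the same set of (tf, gene) pairs.
#'
#' @slot byRegulator named list; each element a sorted character vector of
#'   gene ids significant for that regulator.
#' @slot byGene named list; the transpose of `byRegulator`.
#' @slot alpha numeric(1), the significance threshold used (`NA` when the
#'   input was consumed as a pre-thresholded pair list).
#' @slot datasetKind `"binding"` or `"knockout"`.
#'
#' @seealso [thresholdSignificant()], [transposeMap()], [opForTfSet()]
#' @exportClass SignificantSetMap
setClass("SignificantSetMap",
    slots = c(byRegulator = "list", byGene = "list",
              alpha = "numeric", datasetKind = "character"))

setValidity("SignificantSetMap", function(object) {
    msgs <- character()
    if (!(length(object@datasetKind) == 1L &&
          object@datasetKind %in% .DATASET_KINDS))
        msgs <- c(msgs, "datasetKind must be 'binding' or 'knockout'")
    if (length(object@alpha) != 1L)
        msgs <- c(msgs, "alpha must be a single value")
    pairKey <- function(m, swap = FALSE) {
        if (!length(m)) return(character())
        a <- rep(names(m), lengths(m))
        b <- unlist(m, use.names = FALSE)
        if (swap) sort(paste(b, a, sep = "\r")) else
            sort(paste(a, b, sep = "\r"))
    }
    if (is.null(names(object@byRegulator)) && length(object@byRegulator) ||
        is.null(names(object@byGene)) && length(object@byGene)) {
        msgs <- c(msgs, "set maps must be named lists")
    } else if (!identical(pairKey(object@byRegulator),
                          pairKey(object@byGene, swap = TRUE))) {
        msgs <- c(msgs, "byGene is not the exact transpose of byRegulator")
    }
    if (length(msgs)) msgs else TRUE
})

#' StudyUniverse: the TF and gene universe of an analysis
#'
#' The ordered sets of regulators and genes every downstream overlap
#' computation is restricted to (e.g. the 173 TFs shared between a binding
#' and a knockout dataset, and the genes they touch).
#'
#' @slot tfs character vector of regulator ids (sorted, unique).
#' @slot genes character vector of gene ids (sorted, unique).
#'
#' @seealso [intersectUniverse()]
#' @exportClass StudyUniverse
setClass("StudyUniverse", slots = c(tfs = "character", genes = "character"))

setValidity("StudyUniverse", function(object) {
    msgs <- character()
    if (anyDuplicated(object@tfs) || anyDuplicated(object@genes))
        msgs <- c(msgs, "universe members must be unique")
    if (length(object@tfs) == 0L)
        msgs <- c(msgs, "empty universe: no TFs")
    if (length(msgs)) msgs else TRUE
})

#' AnnotationCatalog: entity -> set of functional annotation terms
#'
#' Flat term sets (GO- or FunCat-style identifiers) per entity, used for the
#' Jaccard functional-similarity computation. Entities with no recorded terms
#' are absent from the map and queried as empty.
#'
#' @slot termsByEntity named list of character vectors of term ids.
#' @slot sourceLabel character(1) naming the catalog (e.g. "GO:BP").
#'
#' @seealso [readAnnotationCatalog()], [functionalSimilarity()]
#' @exportClass AnnotationCatalog
setClass("AnnotationCatalog",
    slots = c(termsByEntity = "list", sourceLabel = "character"))

setValidity("AnnotationCatalog", function(object) {
    msgs <- character()
    m <- object@termsByEntity
    if (length(m)) {
        if (is.null(names(m)) || any(!nzchar(names(m))) ||
            anyDuplicated(names(m)))
            msgs <- c(msgs, "termsByEntity must have unique non-empty names")
        if (any(lengths(m) == 0L))
            msgs <- c(msgs, "entities with no terms must be absent")
        if (any(vapply(m, function(x) any(!nzchar(x)) || anyNA(x),
                       logical(1))))
            msgs <- c(msgs, "term sets contain empty terms")
    }
    if (length(object@sourceLabel) != 1L)
        msgs <- c(msgs, "sourceLabel must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' RedundancyScores: functional-redundancy score per TF
#'
#' FR(t) = max over other TFs q of the Jaccard similarity between the two
#' TFs' annotation term sets, with the maximising partner recorded. TFs that
#' could not be scored (no annotation, or no annotated partner) are listed in
#' `excluded` with a reason, never assigned a score of 0.
#'
#' @slot frByTf named numeric vector of scores in \[0, 1\].
#' @slot argmaxPartner named character vector; `argmaxPartner[t] != t`.
#' @slot excluded data.frame with columns `entity`, `reason`.
#' @slot sourceLabel catalog the scores were computed from.
#'
#' @seealso [scoreAllRedundancy()], [functionalRedundancy()]
#' @exportClass RedundancyScores
setClass("RedundancyScores",
    slots = c(frByTf = "numeric", argmaxPartner = "character",
              excluded = "data.frame", sourceLabel = "character"))

setValidity("RedundancyScores", function(object) {
    msgs <- character()
    fr <- object@frByTf
    if (length(fr) && (anyNA(fr) || any(fr < 0 | fr > 1)))
        msgs <- c(msgs, "FR scores must be in [0,1]")
    if (!identical(names(fr), names(object@argmaxPartner)))
        msgs <- c(msgs, "score and partner names must agree")
    if (length(fr) && any(names(fr) == object@argmaxPartner))
        msgs <- c(msgs, "argmax partner must differ from the TF itself")
    if (length(msgs)) msgs else TRUE
})

#' OverlapResult: pooled overlap-percentage numerator and denominator
#'
#' For a set M of TFs, numerator = sum over t in M of |G_B(t) ∩ G_K(t)| and
#' denominator = sum of |G_B(t)| (and symmetrically over gene sets with
#' T_B/T_K). `op` is their ratio, `NA` when the denominator is zero.
#'
#' @slot numerator integer(1), overlapping pair count.
#' @slot denominator integer(1), binding pair count.
#' @slot op numeric(1) in \[0, 1\] or `NA`.
#' @slot label description of the entity set.
#'
#' @seealso [opForTfSet()], [opForGeneSet()], [proportionTest()]
#' @exportClass OverlapResult
setClass("OverlapResult",
    slots = c(numerator = "integer", denominator = "integer",
              op = "numeric", label = "character"))

setValidity("OverlapResult", function(object) {
    msgs <- character()
    num <- object@numerator; den <- object@denominator
    if (length(num) != 1L || length(den) != 1L || is.na(num) || is.na(den) ||
        num < 0L || den < 0L)
        msgs <- c(msgs, "counts must be single non-negative integers")
    else {
        if (num > den) msgs <- c(msgs, "numerator exceeds denominator")
        if (den > 0L && (is.na(object@op) ||
                         abs(object@op - num / den) > 1e-12))
            msgs <- c(msgs, "op must equal numerator/denominator")
        if (den == 0L && !is.na(object@op))
            msgs <- c(msgs, "op must be NA when denominator is 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' ProportionTestResult: one-sided two-sample proportion test
#'
#' Pooled-variance z statistic comparing the overlap proportions of two
#' entity sets, with a one-sided p-value from the standard normal tail.
#' When the pooled proportion is degenerate (0 or 1) the result is flagged
#' and reported as z = 0, p = 0.5.
#'
#' @slot z numeric(1) test statistic.
#' @slot pValue numeric(1) in (0, 1).
#' @slot group1,group2 the two [OverlapResult-class] objects compared.
#' @slot alternative `"group1_less"` or `"group1_greater"`.
#' @slot degenerate logical(1) flag.
#'
#' @seealso [proportionTest()]
#' @exportClass ProportionTestResult
setClass("ProportionTestResult",
    slots = c(z = "numeric", pValue = "numeric",
              group1 = "OverlapResult", group2 = "OverlapResult",
              alternative = "character", degenerate = "logical"))

setValidity("ProportionTestResult", function(object) {
    msgs <- character()
    if (!(object@alternative %in% c("group1_less", "group1_greater")))
        msgs <- c(msgs, "unknown alternative")
    p <- object@pValue
    if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
        msgs <- c(msgs, "p-value must lie strictly in (0,1)")
    if (length(msgs)) msgs else TRUE
})

#' PropertySpec: layout of one stratified comparison
#'
#' Describes how one TF- or gene-level property is turned into two entity
#' groups: numeric scores split into top/bottom X% strata over a grid of X
#' values, or categorical membership lists compared against each other or
#' against the rest of the universe.
#'
#' @slot name comparison name.
#' @slot level `"tf"` or `"gene"`.
#' @slot mode `"numeric_top_bottom"`, `"categorical_two_lists"` or
#'   `"categorical_vs_rest"`.
#' @slot xGrid numeric vector of X percentages in (0, 50\] (numeric mode).
#' @slot expectedDirection `"first_group_lower"`, `"first_group_higher"` or
#'   `"none"`; the first group is the top stratum (numeric) or list A
#'   (categorical).
#' @slot annotationSource optional catalog label attached to results.
#'
#' @seealso [propertySpec()], [analyzeNumeric()], [analyzeCategorical()]
#' @exportClass PropertySpec
setClass("PropertySpec",
    slots = c(name = "character", level = "character", mode = "character",
              xGrid = "numeric", expectedDirection = "character",
              annotationSource = "character"))

setValidity("PropertySpec", function(object) {
    msgs <- character()
    if (!(object@level %in% c("tf", "gene")))
        msgs <- c(msgs, "level must be 'tf' or 'gene'")
    if (!(object@mode %in% c("numeric_top_bottom", "categorical_two_lists",
                             "categorical_vs_rest")))
        msgs <- c(msgs, "unknown mode")
    if (!(object@expectedDirection %in%
          c("first_group_lower", "first_group_higher", "none")))
        msgs <- c(msgs, "unknown expectedDirection")
    if (object@mode == "numeric_top_bottom") {
        if (!length(object@xGrid) ||
            any(object@xGrid <= 0 | object@xGrid > 50))
            msgs <- c(msgs, "xGrid entries must lie in (0, 50]")
    }
    if (length(msgs)) msgs else TRUE
})

#' AnalysisResult: one stratified comparison, all rows
#'
#' One result row pair per X value (numeric mode) or a single row pair
#' (categorical mode), in the shape of the results table: group overlap
#' counts, overlap percentages, and the one-sided proportion test.
#'
#' @slot spec the [PropertySpec-class] that produced the result.
#' @slot rows data.frame with columns `comparison`, `annotation_source`,
#'   `X`, `side`, `n_entities`, `numerator`, `denominator`, `op`, `z`,
#'   `p_value` (two rows per test, one per group).
#' @slot tests list of [ProportionTestResult-class], one per X / row pair.
#' @slot exclusions data.frame with columns `entity`, `reason`.
#'
#' @seealso [analyzeNumeric()], [analyzeCategorical()], [renderReport()]
#' @exportClass AnalysisResult
setClass("AnalysisResult",
    slots = c(spec = "PropertySpec", rows = "data.frame", tests = "list",
              exclusions = "data.frame"))

setValidity("AnalysisResult", function(object) {
    msgs <- character()
    need <- c("comparison", "annotation_source", "X", "side", "n_entities",
              "numerator", "denominator", "op", "z", "p_value")
    if (!all(need %in% names(object@rows)))
        msgs <- c(msgs, "rows is missing result columns")
    if (object@spec@mode == "numeric_top_bottom") {
        if (nrow(object@rows) != 2L * length(object@spec@xGrid))
            msgs <- c(msgs, "expected one row pair per X in the grid")
    } else if (nrow(object@rows) != 2L)
        msgs <- c(msgs, "categorical comparisons have exactly one row pair")
    if (length(msgs)) msgs else TRUE
})

#' WorldParams: parameters of the synthetic regulatory world
#'
#' All knobs of the generative model behind [generateWorld()]. The defaults
#' emulate the scale of the real yeast study universe (173 TFs, 4065 genes,
#' ~11,400 binding pairs, ~12,000 knockout pairs, overall overlap near 4%)
#' and encode the masking hypothesis: each paralog-paired TF's knockout
#' effects on its bound targets are depressed by `maskingStrength`.
#'
#' @slot nTfs,nGenes integer universe sizes.
#' @slot meanTargetsPerTf Poisson mean of the per-TF bound-gene count.
#' @slot baseEffectProb per-bound-pair knockout-effect probability before
#'   multipliers; `NA` requests the deterministic per-world normalisation
#'   that centres the expected overall overlap at `targetOverallOp`.
#' @slot targetOverallOp overall overlap fraction targeted by normalisation.
#' @slot backgroundEffectProb knockout-effect probability for unbound pairs
#'   (indirect effects).
#' @slot maskingStrength in \[0, 1\]; 0 defines the null world.
#' @slot paralogFraction fraction of TFs placed into high-redundancy pairs.
#' @slot nTerms,termsPerTf,termShareRate annotation-term model: pool size,
#'   terms per TF, and fraction of a pair's terms shared by both members.
#' @slot geneClassEffectMultipliers named multipliers for gene classes
#'   (`tata_containing`, `nfr_containing`, `ribosomal`).
#' @slot tfClassEffectMultipliers named multipliers for TF classes
#'   (`chromatin_remodelling`).
#' @slot classFractions named membership probabilities for the above classes.
#' @slot numericPropertyCoupling named log-odds slopes linking standardized
#'   numeric gene properties to the effect probability.
#' @slot alpha significance threshold emulated by the emitted p-values.
#' @slot significantPScale significant p-values ~ Uniform(0, scale * alpha).
#' @slot nonsigPFloor lower bound of non-significant recorded p-values.
#' @slot nonsigFraction recorded-but-non-significant rows per table, as a
#'   fraction of the significant row count.
#' @slot seed integer seed driving all sampling.
#'
#' @seealso [worldParams()], [nullWorldParams()], [generateWorld()]
#' @exportClass WorldParams
setClass("WorldParams",
    slots = c(nTfs = "integer", nGenes = "integer",
              meanTargetsPerTf = "numeric",
              baseEffectProb = "numeric", targetOverallOp = "numeric",
              backgroundEffectProb = "numeric", maskingStrength = "numeric",
              paralogFraction = "numeric", nTerms = "integer",
              termsPerTf = "integer", termShareRate = "numeric",
              geneClassEffectMultipliers = "numeric",
              tfClassEffectMultipliers = "numeric",
              classFractions = "numeric",
              numericPropertyCoupling = "numeric",
              alpha = "numeric", significantPScale = "numeric",
              nonsigPFloor = "numeric", nonsigFraction = "numeric",
              seed = "integer"))

setValidity("WorldParams", function(object) {
    msgs <- character()
    inUnit <- function(x) all(x >= 0 & x <= 1)
    if (object@nTfs < 4L) msgs <- c(msgs, "nTfs must be >= 4")
    if (object@nGenes < 10L) msgs <- c(msgs, "nGenes must be >= 10")
    if (!inUnit(object@maskingStrength) || !inUnit(object@paralogFraction) ||
        !inUnit(object@backgroundEffectProb) ||
        !inUnit(object@classFractions) || !inUnit(object@termShareRate) ||
        !(is.na(object@baseEffectProb) || inUnit(object@baseEffectProb)))
        msgs <- c(msgs, "probabilities must lie in [0,1]")
    if (any(object@geneClassEffectMultipliers <= 0) ||
        any(object@tfClassEffectMultipliers <= 0))
        msgs <- c(msgs, "class effect multipliers must be positive")
    if (!(object@alpha > 0 && object@alpha <= 1))
        msgs <- c(msgs, "alpha must lie in (0,1]")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticWorld: a complete synthetic study input set
#'
#' Everything the analysis pipeline consumes — binding and knockout
#' interaction tables, an annotation catalog, numeric property tables and
#' categorical class lists — plus the ground truth needed to recompute every
#' realized effect probability.
#'
#' @slot bindingTable,knockoutTable [InteractionTable-class] objects.
#' @slot annotationCatalog [AnnotationCatalog-class].
#' @slot propertyTables named list of data.frames with columns `gene`,
#'   `value`.
#' @slot classLists named list of character vectors (gene or TF ids).
#' @slot truth list: realized base rate, background rate, per-TF and per-gene
#'   multiplicative factors, pairing and class labels.
#' @slot params the [WorldParams-class] used.
#'
#' @seealso [generateWorld()], [writeWorld()], [analyzeWorld()]
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
    slots = c(bindingTable = "InteractionTable",
              knockoutTable = "InteractionTable",
              annotationCatalog = "AnnotationCatalog",
              propertyTables = "list", classLists = "list",
              truth = "list", params = "WorldParams"))
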