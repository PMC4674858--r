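# Accessor generics and show() methods for the core classes.

#' @rdname InteractionTable-class
#' @param x an object
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname InteractionTable-class
#' @export
setMethod("records", "InteractionTable", function(x) x@records)

#' @rdname InteractionTable-class
#' @export
setGeneric("datasetKind", function(x) standardGeneric("datasetKind"))
#' @rdname InteractionTable-class
#' @export
setMethod("datasetKind", "InteractionTable", function(x) x@datasetKind)
#' @rdname SignificantSetMap-class
#' @export
setMethod("datasetKind", "SignificantSetMap", function(x) x@datasetKind)

#' @rdname SignificantSetMap-class
#' @param x an object
#' @export
setGeneric("byRegulator", function(x) standardGeneric("byRegulator"))
#' @rdname SignificantSetMap-class
#' @export
setMethod("byRegulator", "SignificantSetMap", function(x) x@byRegulator)

#' @rdname SignificantSetMap-class
#' @export
setGeneric("byGene", function(x) standardGeneric("byGene"))
#' @rdname SignificantSetMap-class
#' @export
setMethod("byGene", "SignificantSetMap", function(x) x@byGene)

#' @rdname SignificantSetMap-class
#' @export
setGeneric("sigAlpha", function(x) standardGeneric("sigAlpha"))
#' @rdname SignificantSetMap-class
#' @export
setMethod("sigAlpha", "SignificantSetMap", function(x) x@alpha)

#' @rdname StudyUniverse-class
#' @param x an object
#' @export
setGeneric("universeTfs", function(x) standardGeneric("universeTfs"))
#' @rdname StudyUniverse-class
#' @export
setMethod("universeTfs", "StudyUniverse", function(x) x@tfs)

#' @rdname StudyUniverse-class
#' @export
setGeneric("universeGenes", function(x) standardGeneric("universeGenes"))
#' @rdname StudyUniverse-class
#' @export
setMethod("universeGenes", "StudyUniverse", function(x) x@genes)

#' @rdname AnnotationCatalog-class
#' @param x an object
#' @export
setGeneric("termsByEntity", function(x) standardGeneric("termsByEntity"))
#' @rdname AnnotationCatalog-class
#' @export
setMethod("termsByEntity", "AnnotationCatalog", function(x) x@termsByEntity)

#' @rdname AnnotationCatalog-class
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname AnnotationCatalog-class
#' @export
setMethod("sourceLabel", "AnnotationCatalog", function(x) x@sourceLabel)
#' @rdname RedundancyScores-class
#' @export
setMethod("sourceLabel", "RedundancyScores", function(x) x@sourceLabel)

#' @rdname RedundancyScores-class
#' @param x an object
#' @export
setGeneric("frByTf", function(x) standardGeneric("frByTf"))
#' @rdname RedundancyScores-class
#' @export
setMethod("frByTf", "RedundancyScores", function(x) x@frByTf)

#' @rdname RedundancyScores-class
#' @export
setGeneric("argmaxPartner", function(x) standardGeneric("argmaxPartner"))
#' @rdname RedundancyScores-class
#' @export
setMethod("argmaxPartner", "RedundancyScores", function(x) x@argmaxPartner)

#' @rdname RedundancyScores-class
#' @export
setGeneric("excludedEntities", function(x) standardGeneric("excludedEntities"))
#' @rdname RedundancyScores-class
#' @export
setMethod("excludedEntities", "RedundancyScores", function(x) x@excluded)
#' @rdname AnalysisResult-class
#' @export
setMethod("excludedEntities", "AnalysisResult", function(x) x@exclusions)

#' @rdname OverlapResult-class
#' @param x an object
#' @export
setGeneric("opNumerator", function(x) standardGeneric("opNumerator"))
#' @rdname OverlapResult-class
#' @export
setMethod("opNumerator", "OverlapResult", function(x) x@numerator)

#' @rdname OverlapResult-class
#' @export
setGeneric("opDenominator", function(x) standardGeneric("opDenominator"))
#' @rdname OverlapResult-class
#' @export
setMethod("opDenominator", "OverlapResult", function(x) x@denominator)

#' @rdname OverlapResult-class
#' @export
setGeneric("opValue", function(x) standardGeneric("opValue"))
#' @rdname OverlapResult-class
#' @export
setMethod("opValue", "OverlapResult", function(x) x@op)

#' @rdname AnalysisResult-class
#' @param x an object
#' @export
setGeneric("resultRows", function(x) standardGeneric("resultRows"))
#' @rdname AnalysisResult-class
#' @export
setMethod("resultRows", "AnalysisResult", function(x) x@rows)

#' @rdname SyntheticWorld-class
#' @param x an object
#' @export
setGeneric("worldTruth", function(x) standardGeneric("worldTruth"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldTruth", "SyntheticWorld", function(x) x@truth)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldParamsOf", function(x) standardGeneric("worldParamsOf"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldParamsOf", "SyntheticWorld", function(x) x@params)

setMethod("show", "InteractionTable", function(object) {
    cat(sprintf("InteractionTable (%s): %d records, %d regulators, %d genes\n",
        object@datasetKind, nrow(object@records),
        length(unique(object@records$tf)),
        length(unique(object@records$gene))))
})

setMethod("show", "SignificantSetMap", function(object) {
    cat(sprintf(
        "SignificantSetMap (%s, alpha=%s): %d pairs, %d regulators, %d genes\n",
        object@datasetKind, format(object@alpha),
        sum(lengths(object@byRegulator)),
        length(object@byRegulator), length(object@byGene)))
})

setMethod("show", "StudyUniverse", function(object) {
    cat(sprintf("StudyUniverse: %d TFs, %d genes\n",
        length(object@tfs), length(object@genes)))
})

setMethod("show", "AnnotationCatalog", function(object) {
    cat(sprintf(
        "AnnotationCatalog [%s]: %d entities, %d distinct terms\n",
        object@sourceLabel, length(object@termsByEntity),
        length(unique(unlist(object@termsByEntity, use.names = FALSE)))))
})

setMethod("show", "RedundancyScores", function(object) {
    cat(sprintf("RedundancyScores [%s]: %d TFs scored, %d excluded\n",
        object@sourceLabel, length(object@frByTf), nrow(object@excluded)))
    if (length(object@frByTf))
        cat(sprintf("  FR range: %.3f .. %.3f\n",
            min(object@frByTf), max(object@frByTf)))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf("OverlapResult [%s]: %d/%d = %s\n", object@label,
        object@numerator, object@denominator,
        if (is.na(object@op)) "undefined"
        else sprintf("%.1f%%", 100 * object@op)))
})

setMethod("show", "ProportionTestResult", function(object) {
    cat(sprintf(
        "ProportionTestResult: z = %.3f, one-sided p = %.3g (%s)%s\n",
        object@z, object@pValue, object@alternative,
        if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "AnalysisResult", function(object) {
    cat(sprintf("AnalysisResult '%s' (%s-level, %s): %d rows\n",
        object@spec@name, object@spec@level, object@spec@mode,
        nrow(object@rows)))
})

setMethod("show", "WorldParams", function(object) {
    cat(sprintf(
        "WorldParams: %d TFs x %d genes, masking %.2f, seed %d\n",
        object@nTfs, object@nGenes, object@maskingStrength, object@seed))
})

setMethod("show", "SyntheticWorld", function(object) {
    cat(sprintf(
        "SyntheticWorld: %d binding / %d knockout records, %d properties, %d class lists\n",
        nrow(object@bindingTable@records), nrow(object@knockoutTable@records),
        length(object@propertyTables), length(object@classLists)))
})
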