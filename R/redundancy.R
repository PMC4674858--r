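# Functional similarity (Jaccard over annotation term sets) and the
# functional-redundancy score of each TF.

#' Construct an AnnotationCatalog from a named list of term sets
#'
#' @param termsByEntity named list of character vectors of term ids; entries
#'   with zero terms are dropped (entities with no recorded terms are
#'   queried as empty).
#' @param sourceLabel name of the annotation source (e.g. `"GO:BP"`).
#' @return an [AnnotationCatalog-class].
#' @export
annotationCatalog <- function(termsByEntity, sourceLabel = "unnamed") {
    termsByEntity <- lapply(termsByEntity, function(x)
        sort(unique(as.character(x))))
    termsByEntity <- termsByEntity[lengths(termsByEntity) > 0L]
    if (length(termsByEntity))
        termsByEntity <- termsByEntity[order(names(termsByEntity))]
    new("AnnotationCatalog", termsByEntity = termsByEntity,
        sourceLabel = sourceLabel)
}

#' Read an annotation catalog from a two-column TSV
#'
#' Each line associates one entity with one term (`entity<TAB>term`);
#' repeated entity lines accumulate into a term set. Lines starting with
#' `#` are ignored. This is a strict subset of GAF-style association lists.
#'
#' @param path path to the TSV file.
#' @param sourceLabel catalog label; defaults to the file name.
#' @return an [AnnotationCatalog-class].
#' @export
readAnnotationCatalog <- function(path, sourceLabel = basename(path)) {
    if (!file.exists(path))
        stop("missing file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (!length(lines))
        return(annotationCatalog(list(), sourceLabel))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("malformed annotation line in ", path)
    entity <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
    if (any(!nzchar(entity)) || any(!nzchar(term)))
        stop("empty entity or term identifier in ", path)
    annotationCatalog(split(term, entity), sourceLabel)
}

#' Jaccard functional similarity between two term sets
#'
#' FS(t, q) = |A_t ∩ A_q| / |A_t ∪ A_q|. Equals 1 when the two entities
#' carry exactly the same annotation terms and 0 when the sets are disjoint;
#' symmetric in its arguments. Two empty sets have no defined similarity.
#'
#' @param termsT,termsQ character vectors of annotation term ids.
#' @return similarity in \[0, 1\].
#' @examples
#' functionalSimilarity(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
functionalSimilarity <- function(termsT, termsQ) {
    termsT <- unique(as.character(termsT))
    termsQ <- unique(as.character(termsQ))
    u <- length(unique(c(termsT, termsQ)))
    if (u == 0L)
        stop("similarity undefined: both term sets are empty")
    sum(termsT %in% termsQ) / u
}

#' Functional redundancy of one TF
#'
#' FR(t) = max over all other TFs q in the universe of FS(t, q), with the
#' maximising partner reported. A TF has high functional redundancy when
#' some other TF carries a highly similar set of annotation terms — a
#' candidate compensating partner. The maximum excludes q = t, and argmax
#' ties are broken by lexicographic partner id.
#'
#' @param tf regulator id; must be annotated in `catalog`.
#' @param catalog an [AnnotationCatalog-class].
#' @param universeTfs TF ids over which the maximum is taken.
#' @return list with elements `score` (numeric in \[0, 1\]) and `partner`.
#' @examples
#' cat3 <- annotationCatalog(
#'     list(t = c("a", "b", "c"), q = "a", r = c("a", "b")))
#' functionalRedundancy("t", cat3, c("t", "q", "r"))  # score 2/3, partner r
#' @export
functionalRedundancy <- function(tf, catalog, universeTfs) {
    stopifnot(is(catalog, "AnnotationCatalog"))
    if (!(tf %in% universeTfs))
        stop("TF '", tf, "' is not in the universe")
    terms <- catalog@termsByEntity[[tf]]
    if (is.null(terms))
        stop("FR undefined: TF '", tf, "' has no annotation terms")
    others <- setdiff(universeTfs, tf)
    others <- sort(others[others %in% names(catalog@termsByEntity)])
    if (!length(others))
        stop("FR undefined: no annotated partner for TF '", tf, "'")
    sims <- vapply(catalog@termsByEntity[others],
        function(tq) functionalSimilarity(terms, tq), numeric(1))
    best <- max(sims)
    list(score = best, partner = others[which(sims == best)[1L]])
}

#' Functional redundancy of every TF in a universe
#'
#' Applies [functionalRedundancy()] to each TF. TFs without annotation, or
#' without any annotated partner, are excluded with a logged reason rather
#' than scored 0: absence of annotation is missing data, not evidence of
#' functional uniqueness.
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param universeTfs TF ids of the study universe.
#' @return a [RedundancyScores-class].
#' @export
scoreAllRedundancy <- function(catalog, universeTfs) {
    stopifnot(is(catalog, "AnnotationCatalog"))
    universeTfs <- sort(unique(universeTfs))
    annotated <- universeTfs[universeTfs %in% names(catalog@termsByEntity)]
    if (length(annotated) < 2L)
        stop("need at least 2 annotated TFs in the universe")
    fr <- numeric(length(annotated))
    partner <- character(length(annotated))
    termSets <- catalog@termsByEntity[annotated]
    sizes <- lengths(termSets)
    for (i in seq_along(annotated)) {
        # term sets are stored unique, so |A∩B| / (|A| + |B| - |A∩B|)
        # equals the Jaccard coefficient computed by functionalSimilarity()
        ti <- termSets[[i]]
        inter <- vapply(termSets[-i], function(tq) sum(ti %in% tq),
                        numeric(1))
        sims <- inter / (sizes[i] + sizes[-i] - inter)
        fr[i] <- max(sims)
        cand <- names(termSets)[-i][sims == fr[i]]
        partner[i] <- min(cand)
    }
    names(fr) <- annotated
    names(partner) <- annotated
    unann <- setdiff(universeTfs, annotated)
    excluded <- data.frame(
        entity = unann,
        reason = rep("unannotated", length(unann)),
        stringsAsFactors = FALSE)
    new("RedundancyScores", frByTf = fr, argmaxPartner = partner,
        excluded = excluded, sourceLabel = catalog@sourceLabel)
}
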