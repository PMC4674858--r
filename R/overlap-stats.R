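# Overlap-percentage statistics, top/bottom-X% stratification and the
# one-sided two-sample proportion test.

.overlapResult <- function(numerator, denominator, label) {
    numerator <- as.integer(numerator)
    denominator <- as.integer(denominator)
    op <- if (denominator > 0L) numerator / denominator else NA_real_
    if (denominator == 0L)
        warning("overlap percentage undefined for '", label,
                "': zero binding pairs", call. = FALSE)
    new("OverlapResult", numerator = numerator, denominator = denominator,
        op = op, label = label)
}

#' Overlap percentage pooled over a set of TFs
#'
#' For a TF set M, OP = sum over t in M of |G_B(t) ∩ G_K(t)| divided by the
#' sum of |G_B(t)|: the fraction of significant binding pairs whose gene
#' also shows a knockout effect for the same TF. TFs absent from a map
#' contribute empty sets (0 to numerator and denominator).
#'
#' @param tfSet character vector of regulator ids.
#' @param binding,knockout [SignificantSetMap-class] objects (binding and
#'   knockout-effect significant calls).
#' @param label description attached to the result.
#' @return an [OverlapResult-class]; `opValue()` is `NA` (with a warning)
#'   when the TF set has no binding pairs.
#' @seealso [opForGeneSet()], [perEntityOverlap()]
#' @export
opForTfSet <- function(tfSet, binding, knockout, label = "tf_set") {
    stopifnot(is(binding, "SignificantSetMap"),
              is(knockout, "SignificantSetMap"))
    tfSet <- unique(as.character(tfSet))
    .pooledOverlap(binding@byRegulator[tfSet], knockout@byRegulator[tfSet],
                   label)
}

# pooled |bound ∩ affected| / |bound| over pre-subset map selections
# (absent entities select as NULL and contribute empty sets)
.pooledOverlap <- function(bsel, ksel, label) {
    den <- sum(lengths(bsel))
    num <- 0L
    for (i in seq_along(bsel)) {
        b <- bsel[[i]]
        if (is.null(b)) next
        k <- ksel[[i]]
        if (!is.null(k)) num <- num + sum(b %in% k)
    }
    .overlapResult(num, den, label)
}

#' Overlap percentage pooled over a set of genes
#'
#' For a gene set N, OP = sum over g in N of |T_B(g) ∩ T_K(g)| divided by
#' the sum of |T_B(g)|, where T_B(g) is the set of TFs significantly binding
#' g and T_K(g) the set of TFs whose knockout significantly affects g.
#' Genes bound by no TF contribute 0/0 and are effectively excluded.
#'
#' @inheritParams opForTfSet
#' @param geneSet character vector of gene ids.
#' @return an [OverlapResult-class].
#' @export
opForGeneSet <- function(geneSet, binding, knockout, label = "gene_set") {
    stopifnot(is(binding, "SignificantSetMap"),
              is(knockout, "SignificantSetMap"))
    geneSet <- unique(as.character(geneSet))
    .pooledOverlap(binding@byGene[geneSet], knockout@byGene[geneSet], label)
}

#' Per-entity overlap table
#'
#' For every entity (TF or gene) in the universe, the size of its bound
#' set, affected set, their overlap, and the per-entity overlap percentage
#' (`NA` for entities with no binding pairs).
#'
#' @inheritParams opForTfSet
#' @param universe a [StudyUniverse-class].
#' @param level `"tf"` or `"gene"`.
#' @return data.frame with columns `entity`, `n_bound`, `n_affected`,
#'   `n_overlap`, `op`.
#' @export
perEntityOverlap <- function(binding, knockout, universe, level = c("tf", "gene")) {
    level <- match.arg(level)
    stopifnot(is(universe, "StudyUniverse"))
    if (level == "tf") {
        ids <- universe@tfs
        mb <- binding@byRegulator
        mk <- knockout@byRegulator
    } else {
        ids <- universe@genes
        mb <- binding@byGene
        mk <- knockout@byGene
    }
    mb <- unname(mb[ids]); mk <- unname(mk[ids])
    nb <- lengths(mb); nk <- lengths(mk)
    ov <- integer(length(ids))
    for (i in seq_along(ids)) {
        if (nb[i] && nk[i]) ov[i] <- sum(mb[[i]] %in% mk[[i]])
    }
    data.frame(entity = ids, n_bound = nb, n_affected = nk, n_overlap = ov,
        op = ifelse(nb > 0L, ov / nb, NA_real_), stringsAsFactors = FALSE)
}

#' Top or bottom X% stratum of a scored entity set
#'
#' Returns the k = floor(N * X / 100) entities with the largest (`"top"`)
#' or smallest (`"bottom"`) scores. Entities are placed on a single total
#' order (ascending score, ties broken by lexicographic id); the bottom
#' stratum is the head and the top stratum the tail of that order, so top
#' and bottom strata at the same X <= 50 are always disjoint.
#'
#' @param scores named numeric vector of entity scores.
#' @param xPercent stratum size as a percentage in (0, 50\].
#' @param side `"top"` or `"bottom"`.
#' @return character vector of entity ids (sorted).
#' @export
stratifyTopBottom <- function(scores, xPercent, side = c("top", "bottom")) {
    side <- match.arg(side)
    if (!length(scores) || is.null(names(scores)))
        stop("scores must be a non-empty named vector")
    if (!(xPercent > 0 && xPercent <= 50))
        stop("xPercent must lie in (0, 50]")
    k <- floor(length(scores) * xPercent / 100)
    if (k < 1L)
        stop("stratum empty: floor(", length(scores), " * ", xPercent,
             "%) = 0 entities")
    ord <- names(scores)[order(scores, names(scores))]
    sort(if (side == "bottom") utils::head(ord, k) else utils::tail(ord, k))
}

#' One-sided two-sample proportion test on overlap results
#'
#' Pooled-variance z statistic without continuity correction:
#' z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2)) with p the pooled
#' proportion; the one-sided p-value comes from the matching standard
#' normal tail. Each binding pair is treated as an independent Bernoulli
#' trial (a caveat: within-TF correlation is ignored). When the pooled
#' proportion is 0 or 1 the statistic is undefined; by convention the
#' result is z = 0, p = 0.5 with the `degenerate` flag set.
#'
#' @param group1,group2 [OverlapResult-class] objects with positive
#'   denominators.
#' @param alternative `"group1_less"` (p1 < p2) or `"group1_greater"`.
#' @return a [ProportionTestResult-class]. Swapping the groups while
#'   mirroring the alternative negates z and preserves the p-value.
#' @export
proportionTest <- function(group1, group2,
                           alternative = c("group1_less", "group1_greater")) {
    alternative <- match.arg(alternative)
    stopifnot(is(group1, "OverlapResult"), is(group2, "OverlapResult"))
    n1 <- group1@denominator; n2 <- group2@denominator
    if (n1 == 0L || n2 == 0L)
        stop("proportion test requires positive denominators")
    x1 <- group1@numerator; x2 <- group2@numerator
    pooled <- (x1 + x2) / (n1 + n2)
    if (pooled == 0 || pooled == 1) {
        return(new("ProportionTestResult", z = 0, pValue = 0.5,
            group1 = group1, group2 = group2, alternative = alternative,
            degenerate = TRUE))
    }
    z <- (x1 / n1 - x2 / n2) /
        sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- if (alternative == "group1_less") stats::pnorm(z)
         else stats::pnorm(z, lower.tail = FALSE)
    p <- min(max(p, 1e-300), 1 - 1e-12)
    new("ProportionTestResult", z = z, pValue = p, group1 = group1,
        group2 = group2, alternative = alternative, degenerate = FALSE)
}
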