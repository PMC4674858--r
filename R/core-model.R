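# Core model: interaction tables, significance thresholding, universe
# intersection and set-map transposition.

#' Construct an InteractionTable from a data.frame
#'
#' @param records data.frame with columns `tf`, `gene`, `pvalue`.
#' @param datasetKind `"binding"` or `"knockout"`.
#' @return an [InteractionTable-class] object (validated).
#' @examples
#' interactionTable(
#'     data.frame(tf = "TF1", gene = c("g1", "g2"), pvalue = c(0.001, 0.2)),
#'     "binding")
#' @export
interactionTable <- function(records, datasetKind) {
    records <- as.data.frame(records)
    for (col in c("tf", "gene"))
        if (col %in% names(records))
            records[[col]] <- as.character(records[[col]])
    rownames(records) <- NULL
    new("InteractionTable", records = records[c("tf", "gene", "pvalue")],
        datasetKind = datasetKind)
}

#' Read a TF-gene interaction table from a TSV file
#'
#' The file must be tab-separated with a header line `tf  gene  pvalue`
#' (UTF-8, no quoting). Duplicate (tf, gene) rows, p-values outside
#' \[0, 1\] and empty identifiers are errors.
#'
#' @param path path to the TSV file.
#' @param datasetKind `"binding"` or `"knockout"`.
#' @return an [InteractionTable-class].
#' @seealso [writeInteractionTable()], [thresholdSignificant()]
#' @export
readInteractionTable <- function(path, datasetKind) {
    if (!file.exists(path))
        stop("missing file: ", path)
    dat <- utils::read.table(path, header = TRUE, sep = "\t",
        quote = "", comment.char = "", colClasses = "character",
        check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("tf", "gene", "pvalue") %in% names(dat)))
        stop("malformed interaction table ", path,
             ": expected columns tf, gene, pvalue")
    p <- suppressWarnings(as.numeric(dat$pvalue))
    if (anyNA(p))
        stop("malformed row in ", path, ": non-numeric p-value")
    dat$pvalue <- p
    interactionTable(dat, datasetKind)
}

#' Write an InteractionTable to a TSV file
#'
#' Inverse of [readInteractionTable()]: a write followed by a read
#' reproduces identical records.
#'
#' @param table an [InteractionTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractionTable <- function(table, path) {
    stopifnot(is(table, "InteractionTable"))
    utils::write.table(table@records, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a plain-text entity list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path path to the list file.
#' @return character vector of identifiers.
#' @export
readEntityList <- function(path) {
    if (!file.exists(path))
        stop("missing file: ", path)
    x <- readLines(path, warn = FALSE)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a two-column numeric property table
#'
#' Tab-separated with header columns `gene` (or `tf`) and `value`.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of property values.
#' @export
readPropertyTable <- function(path) {
    if (!file.exists(path))
        stop("missing file: ", path)
    dat <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
        comment.char = "", stringsAsFactors = FALSE)
    idCol <- intersect(c("gene", "tf", "entity"), names(dat))[1]
    if (is.na(idCol) || !("value" %in% names(dat)))
        stop("malformed property table ", path,
             ": expected an identifier column and a value column")
    val <- suppressWarnings(as.numeric(dat$value))
    if (anyNA(val))
        stop("malformed row in ", path, ": non-numeric value")
    ids <- as.character(dat[[idCol]])
    if (anyDuplicated(ids))
        stop("duplicate entity in property table ", path)
    stats::setNames(val, ids)
}

.significantSetMapFromPairs <- function(tf, gene, alpha, datasetKind) {
    if (length(tf)) {
        byReg <- lapply(split(gene, tf), function(g) sort(unique(g)))
        byGen <- lapply(split(tf, gene), function(t) sort(unique(t)))
        byReg <- byReg[order(names(byReg))]
        byGen <- byGen[order(names(byGen))]
    } else {
        byReg <- stats::setNames(list(), character())
        byGen <- stats::setNames(list(), character())
    }
    new("SignificantSetMap", byRegulator = byReg, byGene = byGen,
        alpha = alpha, datasetKind = datasetKind)
}

#' Threshold an interaction table into a significant-set map
#'
#' A pair (t, g) is significant when its p-value is strictly below `alpha`
#' (the conventional default is 0.005 for these datasets, the threshold
#' that maximises the binding/knockout overlap). With `alpha = NULL` the
#' table is consumed as a pre-thresholded pair list: every record is taken
#' as significant and the stored threshold is `NA`.
#'
#' @param table an [InteractionTable-class].
#' @param alpha significance threshold in (0, 1\], or `NULL` for
#'   pre-thresholded input.
#' @return a [SignificantSetMap-class]; regulators and genes with no
#'   significant pairs are absent from the maps.
#' @examples
#' tab <- interactionTable(
#'     data.frame(tf = "t1", gene = c("g1", "g2"), pvalue = c(0.001, 0.01)),
#'     "binding")
#' byRegulator(thresholdSignificant(tab, 0.005))
#' @export
thresholdSignificant <- function(table, alpha = 0.005) {
    stopifnot(is(table, "InteractionTable"))
    rec <- table@records
    if (is.null(alpha)) {
        keep <- rep(TRUE, nrow(rec))
        alphaStored <- NA_real_
    } else {
        if (!(is.numeric(alpha) && length(alpha) == 1L &&
              alpha > 0 && alpha <= 1))
            stop("alpha out of range (0, 1]")
        keep <- rec$pvalue < alpha
        alphaStored <- alpha
    }
    .significantSetMapFromPairs(rec$tf[keep], rec$gene[keep],
        alphaStored, table@datasetKind)
}

#' Intersect a binding and a knockout dataset into a study universe
#'
#' The TF universe is the intersection of the two TF sets (e.g. the 173 TFs
#' shared between a 203-TF binding dataset and a 263-strain knockout
#' dataset); the gene universe is the union of genes touched by those TFs in
#' either significant-set map. All downstream overlap computations restrict
#' to this universe.
#'
#' @param binding,knockout [SignificantSetMap-class] objects built at the
#'   same threshold.
#' @param bindingTfs,knockoutTfs the TF sets of the two datasets; default to
#'   the regulators present in each map.
#' @return a [StudyUniverse-class].
#' @export
intersectUniverse <- function(binding, knockout,
                              bindingTfs = names(byRegulator(binding)),
                              knockoutTfs = names(byRegulator(knockout))) {
    stopifnot(is(binding, "SignificantSetMap"),
              is(knockout, "SignificantSetMap"))
    if (!identical(binding@alpha, knockout@alpha))
        stop("binding and knockout maps were built at different thresholds")
    tfs <- sort(intersect(bindingTfs, knockoutTfs))
    if (!length(tfs))
        stop("empty universe: no TF appears in both datasets")
    genes <- sort(unique(c(
        unlist(binding@byRegulator[intersect(tfs, names(binding@byRegulator))],
               use.names = FALSE),
        unlist(knockout@byRegulator[intersect(tfs, names(knockout@byRegulator))],
               use.names = FALSE))))
    new("StudyUniverse", tfs = tfs, genes = genes)
}

#' Transpose a significant-set map
#'
#' Swaps the regulator-keyed and gene-keyed maps, so that after
#' transposition `byRegulator()` is keyed by gene (T_B(g)-style sets).
#' Transposition is an involution and conserves the total pair count.
#'
#' @param map a [SignificantSetMap-class].
#' @return the transposed [SignificantSetMap-class].
#' @export
transposeMap <- function(map) {
    stopifnot(is(map, "SignificantSetMap"))
    new("SignificantSetMap", byRegulator = map@byGene,
        byGene = map@byRegulator, alpha = map@alpha,
        datasetKind = map@datasetKind)
}

#' Restrict a significant-set map to a study universe
#'
#' Drops pairs whose TF is outside `universeTfs(universe)` or whose gene is
#' outside `universeGenes(universe)`.
#'
#' @param map a [SignificantSetMap-class].
#' @param universe a [StudyUniverse-class].
#' @return the restricted [SignificantSetMap-class].
#' @export
restrictToUniverse <- function(map, universe) {
    stopifnot(is(map, "SignificantSetMap"), is(universe, "StudyUniverse"))
    byReg <- map@byRegulator[names(map@byRegulator) %in% universe@tfs]
    byReg <- lapply(byReg, function(g) g[g %in% universe@genes])
    byReg <- byReg[lengths(byReg) > 0L]
    if (length(byReg)) {
        tf <- rep(names(byReg), lengths(byReg))
        gene <- unlist(byReg, use.names = FALSE)
    } else tf <- gene <- character()
    .significantSetMapFromPairs(tf, gene, map@alpha, map@datasetKind)
}
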