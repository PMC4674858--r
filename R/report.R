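# Reporting: results table, plain-text summary, run manifests.

#' Combine analysis results into one results table
#'
#' @param results list of [AnalysisResult-class] objects.
#' @return data.frame with columns `comparison`, `annotation_source`, `X`,
#'   `side`, `n_entities`, `numerator`, `denominator`, `op`, `z`,
#'   `p_value`.
#' @export
resultsTable <- function(results) {
    if (!length(results))
        stop("nothing to report: empty result list")
    do.call(rbind, c(lapply(results, resultRows),
                     list(make.row.names = FALSE)))
}

.formatPercent <- function(op) {
    ifelse(is.na(op), "undefined", sprintf("%.1f%%", 100 * op))
}

#' Write the results table and a plain-text summary
#'
#' `results.tsv` holds every comparison row at full precision;
#' `summary.txt` names each comparison with group overlap percentages
#' (one decimal place) and the one-sided p-value. Reruns on identical
#' inputs produce byte-identical files.
#'
#' @param results list of [AnalysisResult-class] objects.
#' @param outDir output directory (created if needed).
#' @return invisibly, the combined results data.frame.
#' @export
renderReport <- function(results, outDir) {
    tab <- resultsTable(results)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir))
        stop("cannot create directory ", outDir)
    utils::write.table(tab, file.path(outDir, "results.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE, na = "NA")
    lines <- character()
    for (res in results) {
        spec <- res@spec
        header <- sprintf("%s (%s-level, %s)", spec@name, spec@level,
                          spec@mode)
        if (!is.na(spec@annotationSource))
            header <- sprintf("%s [annotations: %s]", header,
                              spec@annotationSource)
        lines <- c(lines, header)
        rows <- res@rows
        for (i in seq(1L, nrow(rows), by = 2L)) {
            r1 <- rows[i, ]; r2 <- rows[i + 1L, ]
            tag <- if (is.na(r1$X)) "" else sprintf("X=%g: ", r1$X)
            lines <- c(lines, sprintf(
                "  %s%s OP %s (%d/%d) vs %s OP %s (%d/%d), z=%.3f, one-sided p=%.3g",
                tag, r1$side, .formatPercent(r1$op), r1$numerator,
                r1$denominator, r2$side, .formatPercent(r2$op),
                r2$numerator, r2$denominator, r1$z, r1$p_value))
        }
        if (nrow(res@exclusions))
            lines <- c(lines, sprintf("  (%d entities excluded)",
                                      nrow(res@exclusions)))
    }
    writeLines(lines, file.path(outDir, "summary.txt"))
    invisible(tab)
}

#' Write a run manifest next to a command's outputs
#'
#' Records the command, a digest of the configuration, digests of every
#' named input file, the seed (if any) and the package version — enough to
#' reproduce the run bit-for-bit.
#'
#' @param outDir output directory.
#' @param command subcommand or function name.
#' @param configPath optional configuration file.
#' @param inputFiles character vector of input file paths.
#' @param seed optional integer seed.
#' @return invisibly, the manifest list.
#' @export
writeRunManifest <- function(outDir, command, configPath = NULL,
                             inputFiles = character(), seed = NULL) {
    digestOf <- function(path)
        if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
    inputs <- lapply(inputFiles, digestOf)
    names(inputs) <- inputFiles
    manifest <- list(
        command = command,
        config = if (is.null(configPath)) NULL else
            list(path = configPath, md5 = digestOf(configPath)),
        inputs = inputs,
        seed = seed,
        tool_version = as.character(utils::packageVersion("TFKOverlap")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(manifest)
}
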