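.fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

.writeTsv <- function(d, path) {
    out <- as.data.frame(lapply(d, .fmt), check.names = FALSE)
    names(out) <- names(d)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}

#' Write a shift result table
#'
#' One TSV row per tissue in ascending rank order; numeric columns carry
#' full precision so identical runs produce byte-identical files.
#'
#' @param sr a [ShiftResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeShiftResult <- function(sr, path) {
    stopifnot(is(sr, "ShiftResult"))
    lead <- c("tissue_id", "lambda_full", "lambda_removed", "delta_lambda",
              "emd", "rank", "block", "group")
    s <- sr@stats[, c(lead, setdiff(names(sr@stats), lead)), drop = FALSE]
    .writeTsv(s, path)
}

#' Write a summary matrix
#'
#' Writes the row-normalized values and the thresholded binary matrix as
#' two TSV files with disease rows and alphabetical tissue columns.
#'
#' @param sm a [SummaryMatrix-class].
#' @param normPath,binaryPath output paths.
#' @return the two paths, invisibly.
#' @export
writeSummary <- function(sm, normPath, binaryPath) {
    stopifnot(is(sm, "SummaryMatrix"))
    dump <- function(m, path, fmt) {
        d <- data.frame(disease = rownames(m), check.names = FALSE)
        for (j in colnames(m)) d[[j]] <- fmt(m[, j])
        write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    eol = "\n")
    }
    dump(sm@normValues, normPath, function(x) sprintf("%.17g", x))
    dump(sm@binary * 1L, binaryPath, as.character)
    invisible(c(normPath, binaryPath))
}

#' Run the full removal pipeline on files
#'
#' Reads a GCT matrix, one or more gene-set files and (optionally) a
#' taxonomy, computes the per-disease tissue shifts, and writes per-disease
#' `shift_*.tsv` and `topblock_*.tsv` tables plus `summary.tsv`,
#' `summary_binary.tsv` and `param_space.tsv` into `outDir`. Gene symbols
#' absent from the matrix are reported via `message()`.
#'
#' @param gctPath path to a GCT 1.2 file.
#' @param geneSetPaths character vector of gene-set CSV/TSV paths; names
#'   (if any) override the disease labels.
#' @param taxonomyPath optional taxonomy YAML/CSV; defaults to the
#'   built-in [gtexTaxonomy()].
#' @param outDir output directory, created if needed.
#' @param config a [shiftConfig()].
#' @param threshold binarization threshold for the summary (default 0.8).
#' @return invisibly, a list with the [ShiftResult-class] objects and the
#'   [SummaryMatrix-class].
#' @export
runPipeline <- function(gctPath, geneSetPaths, taxonomyPath = NULL,
                        outDir = ".", config = shiftConfig(),
                        threshold = 0.8) {
    em <- readGCT(gctPath)
    taxonomy <- if (is.null(taxonomyPath)) gtexTaxonomy()
                else readTaxonomy(taxonomyPath)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    labels <- names(geneSetPaths)
    results <- vector("list", length(geneSetPaths))
    for (i in seq_along(geneSetPaths)) {
        gs <- if (!is.null(labels) && nzchar(labels[i]))
                  readGeneSet(geneSetPaths[i], name = labels[i])
              else readGeneSet(geneSetPaths[i])
        conf <- intersectWithMatrix(gs, em)
        if (conf$nAbsent)
            message("gene set '", gs@setName, "': ", conf$nAbsent,
                    " symbol(s) absent from the matrix (",
                    paste(utils::head(conf$absent, 5L), collapse = ", "),
                    if (conf$nAbsent > 5L) ", ..." else "", ")")
        sr <- computeShift(em, conf$geneSet, taxonomy, config)
        writeShiftResult(sr, file.path(outDir,
            paste0("shift_", .safeName(sr@disease), ".tsv")))
        .writeTsv(topBlock(sr), file.path(outDir,
            paste0("topblock_", .safeName(sr@disease), ".tsv")))
        results[[i]] <- sr
    }
    sm <- buildSummary(results, threshold = threshold)
    writeSummary(sm, file.path(outDir, "summary.tsv"),
                 file.path(outDir, "summary_binary.tsv"))
    if (config$fitGamma) {
        ps <- do.call(rbind, lapply(results, function(sr) {
            s <- sr@stats
            data.frame(disease = sr@disease, tissue_id = s$tissue_id,
                       mean = s$gamma_mean, variance = s$gamma_variance,
                       skewness = s$gamma_skewness,
                       kurtosis = s$gamma_kurtosis,
                       color_value = s$delta_lambda)
        }))
        .writeTsv(ps, file.path(outDir, "param_space.tsv"))
    }
    invisible(list(results = results, summary = sm))
}
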