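#' @rdname TissueExpression-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TissueExpression-class
#' @export
setGeneric("tissueIds", function(x) standardGeneric("tissueIds"))

#' @rdname TissueExpression-class
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname GeneSet-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GeneSet-class
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' @rdname extractPeaks
#' @export
setGeneric("extractPeaks", function(x) standardGeneric("extractPeaks"))

#' @rdname topBlock
#' @export
setGeneric("topBlock", function(x) standardGeneric("topBlock"))

#' @rdname maxTissue
#' @export
setGeneric("maxTissue", function(x) standardGeneric("maxTissue"))

#' @rdname emd1d
#' @export
setGeneric("emd1d", function(x) standardGeneric("emd1d"))

#' @describeIn TissueExpression-class gene identifiers (rownames).
#' @param x a `TissueExpression` (or other object as documented).
#' @export
setMethod("geneIds", "TissueExpression", function(x) rownames(x))

#' @describeIn TissueExpression-class tissue identifiers (colnames).
#' @export
setMethod("tissueIds", "TissueExpression", function(x) colnames(x))

#' @describeIn TissueExpression-class the TPM assay matrix.
#' @export
setMethod("tpm", "TissueExpression", function(x) assay(x, "tpm"))

#' @describeIn GeneSet-class the canonical gene symbols.
#' @param x a `GeneSet`.
#' @export
setMethod("genes", "GeneSet", function(x) x@genes)

#' @describeIn GeneSet-class the per-gene category labels (named character).
#' @export
setMethod("geneScores", "GeneSet", function(x) x@scores)

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@setName, "': ", length(object@genes),
        " genes", sep = "")
    if (length(object@scores))
        cat(" (", length(object@scores), " scored)", sep = "")
    cat("\n")
    if (length(object@genes)) {
        head <- utils::head(object@genes, 6L)
        cat("  ", paste(head, collapse = ", "),
            if (length(object@genes) > 6L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "TissueTaxonomy", function(object) {
    cat("TissueTaxonomy with", nrow(object@mapping), "rules\n")
    for (i in seq_len(min(nrow(object@mapping), 8L)))
        cat(sprintf("  %-28s -> %s\n",
                    sQuote(object@mapping$pattern[i]),
                    object@mapping$group[i]))
})

setMethod("show", "ExponentialFit", function(object) {
    cat(sprintf("ExponentialFit [%s]: lambda = %.6g (n = %d)\n",
                object@tissueId, object@lambda, object@n))
})

setMethod("show", "GammaFit", function(object) {
    cat(sprintf(
        "GammaFit [%s]: shape = %.6g, scale = %.6g (%d zeros dropped)\n",
        object@tissueId, object@shape, object@scale, object@nDropped))
    m <- object@moments
    cat(sprintf("  mean %.4g, variance %.4g, skewness %.4g, ex. kurtosis %.4g\n",
                m["mean"], m["variance"], m["skewness"], m["kurtosis"]))
})

setMethod("show", "ShiftResult", function(object) {
    s <- object@stats
    cat("ShiftResult '", object@disease, "': ", nrow(s), " tissues in ",
        object@nBlocks, " median-ranked blocks\n", sep = "")
    if (nrow(s)) {
        top <- s[s$block == object@nBlocks, ]
        top <- top[order(-top$delta_lambda), ]
        cat("  maximally affected block (", nrow(top), " tissues), top 5:\n",
            sep = "")
        for (i in seq_len(min(5L, nrow(top))))
            cat(sprintf("    %-42s d-lambda %.5g  [%s]\n",
                        top$tissue_id[i], top$delta_lambda[i], top$group[i]))
    }
})

setMethod("show", "SummaryMatrix", function(object) {
    cat("SummaryMatrix: ", length(object@diseaseIds), " diseases x ",
        length(object@tissueIds), " tissues, threshold ", object@threshold,
        "\n", sep = "")
    on <- colSums(object@binary)
    cat("  tissues ON in >= 1 disease: ", sum(on > 0), "\n", sep = "")
})
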