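#' Pipeline configuration
#'
#' Collects the knobs shared by [computeShift()] and the writers.
#'
#' @param nBlocks number of median-ranked blocks (>= 2; default 4, giving a
#'   top block of 13 tissues for the 54 GTEx tissues).
#' @param eq1Variant normalization constant variant, see [normalizeCount()].
#' @param freezeGlobals if `TRUE`, the post-removal series is normalized
#'   with the full-matrix globals instead of recomputing them on the
#'   reduced matrix.
#' @param peaksOnly if `TRUE`, exponential rates are fitted to the strict
#'   local peaks of each normalized series rather than the full series.
#' @param logInput if `TRUE`, `log10(TPM + 1)` feeds the normalization
#'   (exploratory; raw TPM is the default).
#' @param gammaZeroPolicy zero handling for the gamma fit, see [fitGamma()].
#' @param nBins histogram bins for the Earth Mover's Distance (default 32).
#' @param fitGamma if `TRUE` (default), gamma fits of the post-removal
#'   series are included in the result.
#' @return a list of class `ShiftConfig`.
#' @export
shiftConfig <- function(nBlocks = 4L,
                        eq1Variant = c("avg", "avg_over_max"),
                        freezeGlobals = FALSE, peaksOnly = FALSE,
                        logInput = FALSE,
                        gammaZeroPolicy = c("drop", "epsilon"),
                        nBins = 32L, fitGamma = TRUE) {
    stopifnot(nBlocks >= 2L)
    structure(list(nBlocks = as.integer(nBlocks),
                   eq1Variant = match.arg(eq1Variant),
                   freezeGlobals = isTRUE(freezeGlobals),
                   peaksOnly = isTRUE(peaksOnly),
                   logInput = isTRUE(logInput),
                   gammaZeroPolicy = match.arg(gammaZeroPolicy),
                   nBins = as.integer(nBins),
                   fitGamma = isTRUE(fitGamma)),
              class = "ShiftConfig")
}

#' Remove a gene set from an expression matrix
#'
#' Drops the rows of `gs` (which should be confirmed present via
#' [intersectWithMatrix()]); the tissue set is unchanged and the input is
#' untouched.
#'
#' @param em a [TissueExpression-class].
#' @param gs a [GeneSet-class].
#' @return a [TissueExpression-class] without the set's rows.
#' @export
removeGenes <- function(em, gs) {
    stopifnot(is(em, "TissueExpression"), is(gs, "GeneSet"))
    keep <- !(geneIds(em) %in% genes(gs))
    if (!any(keep))
        stop("removal would empty the matrix")
    em[keep, ]
}

#' Median-ranked block sizes
#'
#' Partitions `nTissues` ascending-ranked tissues into `nBlocks` blocks of
#' sizes as equal as possible; when the division is uneven the extra
#' members go to the lowest-rank blocks, so the maximally affected (top)
#' block is the smallest. For 54 tissues in 4 blocks the sizes are
#' 14, 14, 13, 13 and the top block holds 13 tissues.
#'
#' @param nTissues total tissue count.
#' @param nBlocks number of blocks, `2 <= nBlocks <= nTissues`.
#' @return integer vector of block sizes in ascending-rank order.
#' @export
partitionBlocks <- function(nTissues, nBlocks = 4L) {
    nTissues <- as.integer(nTissues); nBlocks <- as.integer(nBlocks)
    if (nBlocks < 2L || nBlocks > nTissues)
        stop("'nBlocks' must be between 2 and the tissue count")
    base <- nTissues %/% nBlocks
    extra <- nTissues %% nBlocks
    sizes <- rep(base, nBlocks)
    if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
    sizes
}

.fitSeries <- function(x, tissue, peaksOnly) {
    if (peaksOnly) {
        x <- x[.peakIdx(x)]
        if (length(x) < 2L)
            stop("fewer than 2 peaks in tissue '", tissue,
                 "'; cannot fit in peaks-only mode")
    }
    fitExponential(x, tissueId = tissue)
}

#' Per-tissue stochastic shift under gene-set removal
#'
#' The core pipeline step: normalizes the full and the reduced matrix,
#' fits the exponential rate per tissue on both, and reports the absolute
#' rate shift `delta_lambda`, the Earth Mover's Distance between the
#' pre/post normalized-count histograms, the ascending rank, the
#' median-ranked block, and the taxonomy group. With an empty (or fully
#' absent) gene set every `delta_lambda` and EMD is exactly zero — the
#' full-genome reference row.
#'
#' Ties in `delta_lambda` are broken by ascending tissue name so reruns are
#' reproducible.
#'
#' @param em the full [TissueExpression-class] matrix.
#' @param gs the disease [GeneSet-class]; genes absent from `em` are
#'   ignored (they cannot be removed).
#' @param taxonomy a [TissueTaxonomy-class]; defaults to [gtexTaxonomy()].
#' @param config a [shiftConfig()].
#' @return a [ShiftResult-class].
#' @export
computeShift <- function(em, gs, taxonomy = gtexTaxonomy(),
                         config = shiftConfig()) {
    stopifnot(is(em, "TissueExpression"), is(gs, "GeneSet"),
              inherits(config, "ShiftConfig"))
    present <- intersectWithMatrix(gs, em)$geneSet

    m <- tpm(em)
    if (config$logInput) m <- log10(m + 1)
    if (length(genes(present))) {
        keep <- !(rownames(m) %in% genes(present))
        if (!any(keep)) stop("removal would empty the matrix")
        mRem <- m[keep, , drop = FALSE]
    } else {
        mRem <- m
    }

    if (max(m) == 0) stop("degenerate all-zero matrix")
    gFull <- list(globalAvg = mean(m), globalMax = max(m))
    gRem <- if (config$freezeGlobals || identical(dim(mRem), dim(m))) gFull
            else list(globalAvg = mean(mRem), globalMax = max(mRem))

    nFull <- .normalizeMat(m, gFull$globalAvg, gFull$globalMax,
                           config$eq1Variant)
    nRem <- .normalizeMat(mRem, gRem$globalAvg, gRem$globalMax,
                          config$eq1Variant)

    tissues <- colnames(m)
    rows <- lapply(tissues, function(t) {
        xF <- nFull[, t]
        xR <- nRem[, t]
        fF <- .fitSeries(xF, t, config$peaksOnly)
        fR <- .fitSeries(xR, t, config$peaksOnly)
        hp <- histogramPair(if (config$peaksOnly) xF[.peakIdx(xF)] else xF,
                            if (config$peaksOnly) xR[.peakIdx(xR)] else xR,
                            nBins = config$nBins)
        out <- data.frame(tissue_id = t, lambda_full = fF@lambda,
                          lambda_removed = fR@lambda,
                          delta_lambda = deltaLambda(fF, fR),
                          emd = emd1d(hp))
        if (config$fitGamma) {
            gf <- tryCatch(
                fitGamma(xR, tissueId = t,
                         zeroPolicy = config$gammaZeroPolicy),
                error = function(e) NULL)
            if (is.null(gf)) {
                out[c("gamma_shape", "gamma_scale", "gamma_mean",
                      "gamma_variance", "gamma_skewness",
                      "gamma_kurtosis")] <- NA_real_
            } else {
                out$gamma_shape <- gf@shape
                out$gamma_scale <- gf@scale
                out$gamma_mean <- gf@moments[["mean"]]
                out$gamma_variance <- gf@moments[["variance"]]
                out$gamma_skewness <- gf@moments[["skewness"]]
                out$gamma_kurtosis <- gf@moments[["kurtosis"]]
            }
        }
        out
    })
    stats <- do.call(rbind, rows)

    ord <- order(stats$delta_lambda, stats$tissue_id, method = "radix")
    stats <- stats[ord, , drop = FALSE]
    rownames(stats) <- NULL
    stats$rank <- seq_len(nrow(stats))
    sizes <- partitionBlocks(nrow(stats), config$nBlocks)
    stats$block <- rep(seq_along(sizes), times = sizes)
    stats$group <- assignGroups(taxonomy, stats$tissue_id)

    new("ShiftResult", disease = gs@setName, stats = stats,
        nBlocks = config$nBlocks)
}

#' Maximally affected tissue block
#'
#' The tissues of the highest median-ranked block, ordered descending by
#' `delta_lambda` (ties by ascending tissue name), with taxonomy labels.
#'
#' @param x a [ShiftResult-class].
#' @return data.frame of the top-block rows.
#' @export
setMethod("topBlock", "ShiftResult", function(x) {
    s <- x@stats[x@stats$block == x@nBlocks, , drop = FALSE]
    s <- s[order(-s$delta_lambda, s$tissue_id, method = "radix"), ,
           drop = FALSE]
    rownames(s) <- NULL
    s
})

#' Most-affected tissue
#'
#' The tissue attaining the maximum `delta_lambda`; ties (including the
#' all-zero reference case) resolve to the first tissue in name order.
#'
#' @param x a [ShiftResult-class].
#' @return list with `tissueId` and `deltaLambda`.
#' @export
setMethod("maxTissue", "ShiftResult", function(x) {
    s <- x@stats
    mx <- max(s$delta_lambda)
    cand <- sort(s$tissue_id[s$delta_lambda == mx], method = "radix")
    list(tissueId = cand[1], deltaLambda = mx)
})
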