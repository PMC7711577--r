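#' Global matrix statistics for the bounded count normalization
#'
#' The normalization constant is built from the overall mean and the overall
#' maximum of the matrix, both taken across every cell.
#'
#' @param em a [TissueExpression-class].
#' @return list with numeric scalars `globalAvg` and `globalMax`.
#' @examples
#' em <- TissueExpression(matrix(c(0, 4, 2, 10), 2,
#'                        dimnames = list(c("A", "B"), c("T1", "T2"))))
#' globalStats(em)  # avg 4, max 10
#' @export
globalStats <- function(em) {
    stopifnot(is(em, "TissueExpression"))
    m <- tpm(em)
    if (!length(m)) stop("empty expression matrix")
    gmax <- max(m)
    if (gmax == 0)
        stop("degenerate all-zero matrix: the normalization is undefined")
    list(globalAvg = mean(m), globalMax = gmax)
}

.normConstant <- function(globalAvg, globalMax,
                          variant = c("avg", "avg_over_max")) {
    variant <- match.arg(variant)
    if (!is.finite(globalAvg) || globalAvg <= 0)
        stop("'globalAvg' must be a positive finite number")
    if (!is.finite(globalMax) || globalMax < globalAvg)
        stop("'globalMax' must be finite and >= 'globalAvg'")
    if (variant == "avg") globalAvg else globalAvg / globalMax
}

#' Bounded normalization of a count value
#'
#' Maps a non-negative count `x` to `x / (x + c)`, a strictly increasing
#' function of the count with range `[0, 1)` that is zero exactly at zero.
#' The constant `c` is `globalAvg` under the default `"avg"` variant, or
#' `globalAvg / globalMax` under `"avg_over_max"` (the literal
#' nested-fraction reading; see the methods vignette for why `"avg"` is the
#' default at TPM scales).
#'
#' @param count non-negative finite numeric (vectorized).
#' @param globalAvg,globalMax global matrix statistics, see [globalStats()].
#' @param variant `"avg"` (default) or `"avg_over_max"`.
#' @return numeric in `[0, 1)`, same length as `count`.
#' @examples
#' normalizeCount(4, 4, 10, variant = "avg_over_max")  # 4 / 4.4
#' @export
normalizeCount <- function(count, globalAvg, globalMax,
                           variant = c("avg", "avg_over_max")) {
    if (any(!is.finite(count)))
        stop("counts must be finite")
    if (any(count < 0))
        stop("counts must be non-negative")
    cc <- .normConstant(globalAvg, globalMax, variant)
    count / (count + cc)
}

.normalizeMat <- function(m, globalAvg, globalMax, variant) {
    cc <- .normConstant(globalAvg, globalMax, variant)
    m / (m + cc)
}

#' Normalized count series of one tissue
#'
#' Applies [normalizeCount()] elementwise down one tissue column, preserving
#' gene order.
#'
#' @param em a [TissueExpression-class].
#' @param tissue a tissue name present in `em`.
#' @param globalAvg,globalMax global statistics; default to [globalStats()]
#'   of `em` itself.
#' @param variant see [normalizeCount()].
#' @return a [NormalizedSeries-class].
#' @export
normalizeTissue <- function(em, tissue, globalAvg = NULL, globalMax = NULL,
                            variant = c("avg", "avg_over_max")) {
    stopifnot(is(em, "TissueExpression"))
    if (!tissue %in% tissueIds(em))
        stop("unknown tissue: ", tissue)
    if (is.null(globalAvg) || is.null(globalMax)) {
        gs <- globalStats(em)
        globalAvg <- gs$globalAvg
        globalMax <- gs$globalMax
    }
    v <- normalizeCount(tpm(em)[, tissue], globalAvg, globalMax, variant)
    new("NormalizedSeries", tissueId = tissue, values = v,
        globalAvg = globalAvg, globalMax = globalMax)
}

.peakIdx <- function(v) {
    n <- length(v)
    if (n < 3L) return(integer())
    mid <- v[2:(n - 1L)]
    unname(which(mid > v[1:(n - 2L)] & mid > v[3:n])) + 1L
}

#' Strict local maxima of a normalized series
#'
#' A peak is an interior element strictly greater than both neighbours;
#' plateaus therefore yield no peak. Series shorter than 3, or monotone
#' series, give an empty result.
#'
#' @param x a [NormalizedSeries-class] (or a bare numeric vector).
#' @return a [PeakSeries-class].
#' @export
setMethod("extractPeaks", "NormalizedSeries", function(x) {
    idx <- .peakIdx(x@values)
    new("PeakSeries", tissueId = x@tissueId, peakIndices = idx,
        peakValues = unname(x@values[idx]))
})

#' @rdname extractPeaks
#' @export
setMethod("extractPeaks", "numeric", function(x) {
    idx <- .peakIdx(x)
    new("PeakSeries", tissueId = NA_character_, peakIndices = idx,
        peakValues = unname(x[idx]))
})
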