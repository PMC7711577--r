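#' Exponential maximum-likelihood fit
#'
#' The exponential rate MLE has the closed form `lambda = 1 / mean(x)`:
#' maximizing `L(lambda | x_1..x_n) = prod lambda * exp(-lambda * x_i)` in
#' `lambda` gives `n / sum(x_i)` analytically, so no iteration is needed.
#'
#' @param values non-negative numeric vector, length >= 2, positive mean.
#' @param tissueId optional tissue label carried on the fit.
#' @return an [ExponentialFit-class].
#' @examples
#' fitExponential(c(0.25, 0.75))  # lambda = 2
#' @export
fitExponential <- function(values, tissueId = NA_character_) {
    if (length(values) < 2L)
        stop("need at least 2 values to fit")
    if (any(!is.finite(values)))
        stop("values must be finite")
    if (any(values < 0))
        stop("values must be non-negative")
    m <- mean(values)
    if (m <= 0)
        stop("degenerate all-zero sample: the rate is undefined")
    new("ExponentialFit", tissueId = tissueId, lambda = 1 / m,
        n = length(values))
}

#' Closed-form gamma moments
#'
#' @param shape,scale positive gamma parameters.
#' @return named numeric: mean `a*b`, variance `a*b^2`, skewness
#'   `2/sqrt(a)`, excess kurtosis `6/a`.
#' @export
gammaMoments <- function(shape, scale) {
    stopifnot(shape > 0, scale > 0)
    c(mean = shape * scale, variance = shape * scale^2,
      skewness = 2 / sqrt(shape), kurtosis = 6 / shape)
}

#' Gamma maximum-likelihood fit
#'
#' Solves the profile likelihood equation
#' `log(a) - digamma(a) = log(mean(x)) - mean(log(x))` by Newton iteration
#' from the standard closed-form starting value, then sets
#' `scale = mean(x) / a`. Zeros (normalized counts of unexpressed genes)
#' are outside the gamma support; under the default `"drop"` policy they
#' are excluded and counted, under `"epsilon"` they are replaced by half
#' the smallest positive value.
#'
#' @param values non-negative numeric vector.
#' @param tissueId optional tissue label.
#' @param zeroPolicy `"drop"` (default) or `"epsilon"`.
#' @param maxIter,tol Newton iteration controls.
#' @return a [GammaFit-class].
#' @export
fitGamma <- function(values, tissueId = NA_character_,
                     zeroPolicy = c("drop", "epsilon"),
                     maxIter = 100L, tol = 1e-12) {
    zeroPolicy <- match.arg(zeroPolicy)
    if (any(!is.finite(values)))
        stop("values must be finite")
    if (any(values < 0))
        stop("values must be non-negative")
    zero <- values == 0
    nDropped <- 0L
    if (any(zero)) {
        if (zeroPolicy == "drop") {
            nDropped <- sum(zero)
            values <- values[!zero]
        } else {
            if (all(zero))
                stop("all values are zero; gamma fit is undefined")
            values[zero] <- min(values[!zero]) / 2
        }
    }
    if (length(values) < 2L)
        stop("need at least 2 positive values to fit")
    mbar <- mean(values)
    s <- log(mbar) - mean(log(values))
    if (!is.finite(s) || s <= 0)
        stop("degenerate sample (zero log-dispersion); gamma fit undefined")
    # standard closed-form initial value, then Newton on
    # f(a) = log(a) - digamma(a) - s
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        f <- log(a) - digamma(a) - s
        fp <- 1 / a - trigamma(a)
        step <- f / fp
        aNew <- a - step
        if (aNew <= 0) aNew <- a / 2
        if (abs(aNew - a) <= tol * max(1, a)) {
            a <- aNew
            converged <- TRUE
            break
        }
        a <- aNew
    }
    if (!converged)
        stop(sprintf(paste0("gamma fit did not converge in %d iterations ",
                            "(last shape %.6g, s = %.6g)"), maxIter, a, s))
    b <- mbar / a
    new("GammaFit", tissueId = tissueId, shape = a, scale = b,
        moments = gammaMoments(a, b), nDropped = nDropped)
}

#' Gamma log-likelihood of a sample
#'
#' @param values positive numeric vector.
#' @param shape,scale gamma parameters.
#' @return the log-likelihood.
#' @export
gammaLogLik <- function(values, shape, scale) {
    sum(stats::dgamma(values, shape = shape, scale = scale, log = TRUE))
}

#' Build a histogram pair on shared bin edges
#'
#' Bins both samples over `nBins` equal-width bins spanning
#' `[0, max(before, after)]` and normalizes each to unit mass. If both
#' samples are identically zero the single degenerate bin `[0, 1]` is used.
#'
#' @param before,after non-negative numeric samples.
#' @param nBins number of equal-width bins (default 32).
#' @return a [HistogramPair-class].
#' @export
histogramPair <- function(before, after, nBins = 32L) {
    stopifnot(length(before) > 0, length(after) > 0)
    hi <- max(before, after)
    if (hi <= 0) hi <- 1
    edges <- seq(0, hi, length.out = nBins + 1L)
    new("HistogramPair", binEdges = edges,
        freqBefore = .binFreq(before, edges),
        freqAfter = .binFreq(after, edges))
}

.binFreq <- function(x, edges) {
    nb <- length(edges) - 1L
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = nb) / length(x)
}

#' Earth Mover's Distance between two binned distributions
#'
#' The 1-D Wasserstein-1 distance on binned mass:
#' `sum_k |CDF_before(k) - CDF_after(k)| * width_k`. On shared edges this
#' equals the minimal-cost transport between the two histograms.
#'
#' @param x a [HistogramPair-class].
#' @return non-negative numeric distance.
#' @export
setMethod("emd1d", "HistogramPair", function(x) {
    widths <- diff(x@binEdges)
    sum(abs(cumsum(x@freqBefore - x@freqAfter)) * widths)
})

#' Absolute rate shift between two exponential fits
#'
#' `|lambda_full - lambda_removed|` for the same tissue: the per-tissue
#' stochastic-shift statistic of the pipeline. Symmetric in its arguments
#' and zero iff the rates are equal.
#'
#' @param full,removed [ExponentialFit-class] objects for the same tissue.
#' @return non-negative numeric.
#' @export
deltaLambda <- function(full, removed) {
    stopifnot(is(full, "ExponentialFit"), is(removed, "ExponentialFit"))
    if (!identical(full@tissueId, removed@tissueId))
        stop("fits are for different tissues: ", full@tissueId, " vs ",
             removed@tissueId)
    abs(full@lambda - removed@lambda)
}
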