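#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom stats rlnorm runif rexp binom.test digamma trigamma setNames
#' @importFrom utils read.delim write.table
NULL

.TAXONOMY_GROUPS <- c("CNS", "heart", "muscle_skeletal", "peripheral_organ")

#' Gene-by-tissue TPM expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay,
#' `"tpm"`: a non-negative, finite matrix of expression values with genes as
#' rows and tissues as columns. Gene identifiers (rownames) are canonical
#' upper-case symbols and unique; tissue identifiers (colnames) are unique.
#'
#' @seealso [TissueExpression()] for the constructor, [readGCT()] to load a
#'   GCT 1.2 file.
#' @export
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
    msg <- character()
    if (!"tpm" %in% assayNames(object)) {
        return("assay 'tpm' is required")
    }
    a <- assay(object, "tpm")
    if (!is.numeric(a))
        msg <- c(msg, "'tpm' values must be numeric")
    else {
        if (any(!is.finite(a)))
            msg <- c(msg, "'tpm' values must be finite")
        else if (any(a < 0))
            msg <- c(msg, "'tpm' values must be non-negative")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) are required")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers after canonicalization")
    if (is.null(colnames(object)))
        msg <- c(msg, "tissue identifiers (colnames) are required")
    else if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate tissue identifiers")
    if (length(msg)) msg else TRUE
})

#' Disease gene set
#'
#' A named collection of canonical gene symbols for one disease, with
#' optional per-gene category labels (e.g. SFARI scores "1", "2S") carried
#' as pass-through metadata.
#'
#' @slot setName single character, the disease label.
#' @slot genes character vector of unique canonical gene symbols (may be
#'   empty, e.g. after an empty intersection).
#' @slot scores named character vector; names are a subset of `genes`.
#' @export
setClass("GeneSet",
    representation(setName = "character", genes = "character",
                   scores = "character"),
    prototype(setName = NA_character_, genes = character(),
              scores = setNames(character(), character())))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@setName) != 1L)
        msg <- c(msg, "'setName' must be a single string")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene symbols must be unique")
    if (length(object@scores) &&
        (is.null(names(object@scores)) ||
         !all(names(object@scores) %in% object@genes)))
        msg <- c(msg, "score names must be a subset of the gene symbols")
    if (length(msg)) msg else TRUE
})

#' Tissue taxonomy
#'
#' An ordered list of case-insensitive substring patterns mapping tissue
#' names to one of the four groups `CNS`, `heart`, `muscle_skeletal`,
#' `peripheral_organ`. Patterns are evaluated in order; the first match wins.
#' An empty pattern `""` matches every tissue and can serve as a catch-all.
#'
#' @slot mapping data.frame with character columns `pattern` and `group`.
#' @export
setClass("TissueTaxonomy", representation(mapping = "data.frame"))

setValidity("TissueTaxonomy", function(object) {
    m <- object@mapping
    msg <- character()
    if (!all(c("pattern", "group") %in% names(m)))
        msg <- c(msg, "'mapping' needs columns 'pattern' and 'group'")
    else if (!all(m$group %in% .TAXONOMY_GROUPS))
        msg <- c(msg, paste0("groups must be one of: ",
                             paste(.TAXONOMY_GROUPS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Normalized count series for one tissue
#'
#' Per-gene bounded normalized counts `x / (x + c)` for one tissue column,
#' together with the global statistics that define the constant `c`.
#' Every value lies in `[0, 1)` and is zero exactly where the TPM is zero.
#'
#' @slot tissueId single character.
#' @slot values named numeric vector (gene order preserved), each in `[0,1)`.
#' @slot globalAvg,globalMax the global mean and maximum of the matrix the
#'   series was normalized against.
#' @export
setClass("NormalizedSeries",
    representation(tissueId = "character", values = "numeric",
                   globalAvg = "numeric", globalMax = "numeric"))

setValidity("NormalizedSeries", function(object) {
    v <- object@values
    if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v >= 1)))
        return("normalized values must lie in [0, 1)")
    TRUE
})

#' Strict local maxima of a normalized series
#'
#' Indices and values of interior points strictly exceeding both neighbours.
#'
#' @slot tissueId single character.
#' @slot peakIndices strictly increasing integer indices, none at either end
#'   of the parent series.
#' @slot peakValues numeric, same length as `peakIndices`.
#' @export
setClass("PeakSeries",
    representation(tissueId = "character", peakIndices = "integer",
                   peakValues = "numeric"))

setValidity("PeakSeries", function(object) {
    if (length(object@peakIndices) != length(object@peakValues))
        return("indices and values must have equal length")
    if (is.unsorted(object@peakIndices, strictly = TRUE))
        return("peak indices must be strictly increasing")
    TRUE
})

#' Exponential maximum-likelihood fit
#'
#' Rate parameter of the exponential model fitted to a normalized-count
#' series; the MLE is the reciprocal sample mean.
#'
#' @slot tissueId single character.
#' @slot lambda positive rate.
#' @slot n sample size used in the fit.
#' @export
setClass("ExponentialFit",
    representation(tissueId = "character", lambda = "numeric", n = "integer"))

setValidity("ExponentialFit", function(object) {
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0)
        return("'lambda' must be a single positive finite number")
    TRUE
})

#' Gamma maximum-likelihood fit with closed-form moments
#'
#' Shape/scale parameters maximizing the gamma likelihood, plus the four
#' moments in closed form: mean `a*b`, variance `a*b^2`, skewness `2/sqrt(a)`
#' and excess kurtosis `6/a`.
#'
#' @slot tissueId single character.
#' @slot shape,scale positive parameters.
#' @slot moments named numeric of length 4
#'   (`mean`, `variance`, `skewness`, `kurtosis`).
#' @slot nDropped number of zero values excluded under the `"drop"` policy.
#' @export
setClass("GammaFit",
    representation(tissueId = "character", shape = "numeric",
                   scale = "numeric", moments = "numeric",
                   nDropped = "integer"))

setValidity("GammaFit", function(object) {
    if (object@shape <= 0 || object@scale <= 0)
        return("'shape' and 'scale' must be positive")
    a <- object@shape; b <- object@scale
    want <- c(mean = a * b, variance = a * b^2,
              skewness = 2 / sqrt(a), kurtosis = 6 / a)
    if (length(object@moments) != 4L ||
        !isTRUE(all.equal(unname(object@moments), unname(want),
                          tolerance = 1e-10)))
        return("'moments' must equal the closed forms of shape and scale")
    TRUE
})

#' Pair of histograms on shared bin edges
#'
#' Two frequency vectors over identical increasing bin edges, each
#' normalized to unit mass; the input to the Earth Mover's Distance.
#'
#' @slot binEdges increasing numeric, length nbins + 1.
#' @slot freqBefore,freqAfter non-negative numeric summing to 1.
#' @export
setClass("HistogramPair",
    representation(binEdges = "numeric", freqBefore = "numeric",
                   freqAfter = "numeric"))

setValidity("HistogramPair", function(object) {
    e <- object@binEdges
    if (length(e) < 2L || is.unsorted(e, strictly = TRUE))
        return("'binEdges' must be strictly increasing, length >= 2")
    nb <- length(e) - 1L
    for (s in c("freqBefore", "freqAfter")) {
        f <- slot(object, s)
        if (length(f) != nb)
            return(sprintf("'%s' must have one value per bin", s))
        if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
            return(sprintf("'%s' must be non-negative and sum to 1", s))
    }
    TRUE
})

#' Per-disease tissue shift result
#'
#' One row per tissue with the rate shift `deltaLambda`, the Earth Mover's
#' Distance between pre/post normalized-count histograms, the ascending
#' rank, the median-ranked block (block `nBlocks` holds the maximally
#' affected tissues), the taxonomy group, and (optionally) the gamma fit of
#' the post-removal series. Rows are stored in ascending rank order.
#'
#' @slot disease single character, the disease label.
#' @slot stats data.frame of per-tissue statistics.
#' @slot nBlocks number of median-ranked blocks used.
#' @export
setClass("ShiftResult",
    representation(disease = "character", stats = "data.frame",
                   nBlocks = "integer"))

setValidity("ShiftResult", function(object) {
    need <- c("tissue_id", "lambda_full", "lambda_removed", "delta_lambda",
              "emd", "rank", "block", "group")
    s <- object@stats
    if (!all(need %in% names(s)))
        return(paste0("stats must contain columns: ",
                      paste(need, collapse = ", ")))
    if (nrow(s) && !identical(sort(s$rank), seq_len(nrow(s))))
        return("ranks must be a permutation of 1..T")
    if (nrow(s) && any(s$delta_lambda < 0))
        return("delta_lambda must be non-negative")
    TRUE
})

#' Disease-by-tissue summary of normalized rate shifts
#'
#' Rows are diseases (first row a full-genome reference of exact zeros),
#' columns are tissues in alphabetical order. `normValues` holds each row's
#' delta-lambda divided by the row maximum (all-zero rows stay zero);
#' `binary` is `normValues > threshold` elementwise (strict).
#'
#' @slot diseaseIds,tissueIds character row/column labels.
#' @slot raw,normValues numeric matrices; `binary` logical matrix.
#' @slot threshold single numeric in `[0, 1]`.
#' @export
setClass("SummaryMatrix",
    representation(diseaseIds = "character", tissueIds = "character",
                   raw = "matrix", normValues = "matrix", binary = "matrix",
                   threshold = "numeric"))

setValidity("SummaryMatrix", function(object) {
    d <- c(length(object@diseaseIds), length(object@tissueIds))
    for (s in c("raw", "normValues", "binary"))
        if (!identical(dim(slot(object, s)), as.integer(d)))
            return(sprintf("'%s' dimensions must match labels", s))
    if (any(object@normValues < 0) || any(object@normValues > 1))
        return("'normValues' must lie in [0, 1]")
    if (!all(object@binary == (object@normValues > object@threshold)))
        return("'binary' must equal normValues > threshold (strict)")
    TRUE
})
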