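#' Disease x tissue summary of normalized rate shifts
#'
#' Stacks per-disease shift results into a matrix with tissues as columns
#' (alphabetical order) and diseases as rows, prefixed by a full-genome
#' reference row of exact zeros. Each row is divided by its maximum (the
#' row's most-affected tissue scores 1; all-zero rows stay zero with a
#' warning) and binarized with a strict `> threshold` comparison.
#'
#' @param results list of [ShiftResult-class] objects sharing one tissue
#'   set.
#' @param threshold binarization cutoff in `[0, 1]` (default 0.8).
#' @param referenceLabel row label for the zero reference row.
#' @return a [SummaryMatrix-class].
#' @export
buildSummary <- function(results, threshold = 0.8,
                         referenceLabel = "full_genome") {
    stopifnot(length(results) > 0,
              all(vapply(results, is, logical(1), "ShiftResult")))
    tissues <- sort(results[[1]]@stats$tissue_id, method = "radix")
    for (r in results)
        if (!setequal(r@stats$tissue_id, tissues))
            stop("shift results do not share the same tissue set")
    diseases <- vapply(results, function(r) r@disease, character(1))
    if (anyDuplicated(diseases))
        stop("duplicate disease labels in results")

    raw <- matrix(0, nrow = length(results) + 1L, ncol = length(tissues),
                  dimnames = list(c(referenceLabel, diseases), tissues))
    for (i in seq_along(results)) {
        s <- results[[i]]@stats
        raw[i + 1L, s$tissue_id] <- s$delta_lambda
    }
    rowMax <- apply(raw, 1L, max)
    zeroRows <- rowMax == 0
    if (any(zeroRows & rownames(raw) != referenceLabel))
        warning("all-zero delta-lambda row(s) left unnormalized: ",
                paste(rownames(raw)[zeroRows & rownames(raw) !=
                                        referenceLabel], collapse = ", "))
    norm <- raw / ifelse(rowMax == 0, 1, rowMax)
    new("SummaryMatrix", diseaseIds = rownames(raw), tissueIds = tissues,
        raw = raw, normValues = norm, binary = norm > threshold,
        threshold = threshold)
}

#' Thresholded overlap between disease groups
#'
#' For two groups of diseases, reports the tissues that are ON (normalized
#' shift above threshold) in every member of each group, plus their
#' intersection and set differences.
#'
#' @param sm a [SummaryMatrix-class].
#' @param groupA,groupB character vectors of disease labels present in
#'   `sm`.
#' @return list with `commonA`, `commonB`, `intersection`, `onlyA`,
#'   `onlyB` (character vectors of tissue names).
#' @export
overlapReport <- function(sm, groupA, groupB) {
    stopifnot(is(sm, "SummaryMatrix"))
    unknown <- setdiff(c(groupA, groupB), sm@diseaseIds)
    if (length(unknown))
        stop("unknown disease label(s): ", paste(unknown, collapse = ", "))
    onSet <- function(group) {
        hits <- sm@binary[group, , drop = FALSE]
        sm@tissueIds[colSums(hits) == length(group)]
    }
    a <- onSet(groupA)
    b <- onSet(groupB)
    list(commonA = a, commonB = b, intersection = intersect(a, b),
         onlyA = setdiff(a, b), onlyB = setdiff(b, a))
}

#' Gamma parameter-space coordinates
#'
#' One point per tissue in the moment space used to visualize stochastic
#' shifts: mean, variance and skewness as axes, excess kurtosis as marker
#' size, and a caller-supplied per-tissue value (rate shift or EMD) as
#' colour. Coordinates are the closed-form moments of each tissue's gamma
#' fit.
#'
#' @param fits list of [GammaFit-class] objects.
#' @param colors named numeric, tissue -> colour value; every tissue must
#'   have a fit.
#' @return data.frame with columns `tissue_id`, `mean`, `variance`,
#'   `skewness`, `kurtosis`, `color_value`.
#' @export
paramSpace <- function(fits, colors) {
    stopifnot(all(vapply(fits, is, logical(1), "GammaFit")))
    fitIds <- vapply(fits, function(f) f@tissueId, character(1))
    missing <- setdiff(names(colors), fitIds)
    if (length(missing))
        stop("no gamma fit for tissue(s): ", paste(missing, collapse = ", "))
    idx <- match(names(colors), fitIds)
    do.call(rbind, lapply(seq_along(idx), function(i) {
        f <- fits[[idx[i]]]
        data.frame(tissue_id = f@tissueId,
                   mean = f@moments[["mean"]],
                   variance = f@moments[["variance"]],
                   skewness = f@moments[["skewness"]],
                   kurtosis = f@moments[["kurtosis"]],
                   color_value = unname(colors[i]))
    }))
}
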