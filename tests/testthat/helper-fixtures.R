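# Small in-code fixtures and independent oracles shared across tests.

# genes x tissues matrix with deterministic values
tinyMatrix <- function(nGenes = 10, nTissues = 4, seed = 42) {
    set.seed(seed)
    m <- matrix(rlnorm(nGenes * nTissues, 0, 1), nGenes, nTissues,
                dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                                sprintf("Tissue%02d", seq_len(nTissues))))
    TissueExpression(m)
}

# exhaustive interior scan for strict local maxima
peakScanOracle <- function(v) {
    idx <- integer()
    for (i in seq_along(v)) {
        if (i == 1L || i == length(v)) next
        if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) idx <- c(idx, i)
    }
    idx
}

# Wasserstein-1 between two histograms with integer counts on shared
# equal-width bins: expand each histogram into unit masses at bin centers,
# sort, and average the absolute differences. Optimal 1-D transport equals
# this quantile coupling, so it is an independent check on the CDF formula.
emdExpansionOracle <- function(countsA, countsB, edges) {
    stopifnot(sum(countsA) == sum(countsB))
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    a <- rep(centers, countsA)
    b <- rep(centers, countsB)
    mean(abs(sort(a) - sort(b)))
}
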