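test_that("gene removal drops exactly the set's rows", {
    em <- tinyMatrix(10, 4)
    gs <- GeneSet("d", geneIds(em)[c(1, 4, 9)])
    rem <- removeGenes(em, gs)
    expect_identical(dim(rem), c(7L, 4L))
    expect_identical(tissueIds(rem), tissueIds(em))
    expect_false(any(genes(gs) %in% geneIds(rem)))
    # empty removal is the identity
    expect_identical(tpm(removeGenes(em, GeneSet("e", character()))),
                     tpm(em))
    # original untouched; rows recoverable
    expect_identical(dim(em), c(10L, 4L))
    expect_identical(tpm(em)[geneIds(rem), ], tpm(rem))
    expect_error(removeGenes(em, GeneSet("all", geneIds(em))), "empty")
})

test_that("median-ranked block sizes are forced by the smallest-top rule", {
    expect_identical(partitionBlocks(54, 4), c(14L, 14L, 13L, 13L))
    expect_identical(partitionBlocks(8, 4), rep(2L, 4))
    expect_identical(partitionBlocks(7, 4), c(2L, 2L, 2L, 1L))
    expect_identical(sum(partitionBlocks(91, 5)), 91L)
    expect_error(partitionBlocks(3, 4), "between")
})

test_that("an empty removal yields the exact zero reference", {
    em <- tinyMatrix(50, 6)
    sr <- computeShift(em, GeneSet("reference", character()))
    expect_true(all(sr@stats$delta_lambda == 0))
    expect_true(all(sr@stats$emd == 0))
    expect_identical(sort(sr@stats$rank), 1:6)
    # all-tied ranking falls back to name order
    expect_identical(sr@stats$tissue_id,
                     sort(tissueIds(em), method = "radix"))
    mt <- maxTissue(sr)
    expect_identical(mt$tissueId, sort(tissueIds(em), method = "radix")[1])
    expect_identical(mt$deltaLambda, 0)
})

test_that("a tissue-exclusive gene set maximally shifts that tissue", {
    # disease genes expressed ONLY in the target tissue: removal changes
    # only that tissue's count distribution (under frozen globals)
    set.seed(99)
    m <- matrix(rlnorm(200 * 8, 0, 1), 200, 8,
                dimnames = list(sprintf("G%03d", 1:200),
                                sprintf("Tissue%02d", 1:8)))
    dg <- sprintf("G%03d", 1:20)
    m[dg, ] <- 0
    m[dg, "Tissue05"] <- rlnorm(20, 3, 1)
    em <- TissueExpression(m)
    cfg <- shiftConfig(freezeGlobals = TRUE, fitGamma = FALSE)
    sr <- computeShift(em, GeneSet("planted", dg), config = cfg)
    expect_identical(maxTissue(sr)$tissueId, "Tissue05")
    others <- sr@stats[sr@stats$tissue_id != "Tissue05", ]
    expect_true(all(others$delta_lambda < maxTissue(sr)$deltaLambda))
})

test_that("rank order, blocks and taxonomy annotate consistently", {
    cfg <- syntheticConfig(nGenes = 400, seed = 21,
        diseaseSets = list(list(name = "d", size = 40,
                                targetTissues = "Brain - Cortex",
                                fold = 50)))
    em <- generateMatrix(cfg)
    gs <- generateGeneSets(cfg)$d
    sr <- computeShift(em, gs, config = shiftConfig(fitGamma = FALSE))
    s <- sr@stats
    expect_identical(s$rank, 1:54)
    expect_true(all(diff(s$delta_lambda) >= 0))      # ascending
    expect_identical(as.integer(table(s$block)), c(14L, 14L, 13L, 13L))
    expect_true(all(s$block == rep(1:4, c(14, 14, 13, 13))))
    expect_identical(s$group,
                     assignGroups(gtexTaxonomy(), s$tissue_id))
    tb <- topBlock(sr)
    expect_identical(nrow(tb), 13L)
    expect_true(all(diff(tb$delta_lambda) <= 0))     # descending
    expect_identical(sort(tb$tissue_id),
                     sort(s$tissue_id[s$block == 4]))
    # max tissue equals an exhaustive scan
    expect_identical(maxTissue(sr)$tissueId,
                     s$tissue_id[which.max(s$delta_lambda)])
})

test_that("the shift is invariant to gene order in full-series mode", {
    em <- tinyMatrix(60, 5)
    gs <- GeneSet("d", geneIds(em)[c(3, 10, 30)])
    sr1 <- computeShift(em, gs, config = shiftConfig(fitGamma = FALSE))
    perm <- sample(nrow(em))
    em2 <- TissueExpression(tpm(em)[perm, ])
    sr2 <- computeShift(em2, gs, config = shiftConfig(fitGamma = FALSE))
    expect_equal(sr1@stats$delta_lambda, sr2@stats$delta_lambda)
    expect_identical(sr1@stats$tissue_id, sr2@stats$tissue_id)
})

test_that("peaks-only mode fits the local maxima of each series", {
    em <- tinyMatrix(300, 3, seed = 77)
    gs <- GeneSet("d", geneIds(em)[1:30])
    cfg <- shiftConfig(peaksOnly = TRUE, fitGamma = FALSE, nBlocks = 2)
    sr <- computeShift(em, gs, config = cfg)
    # reproduce one tissue's lambda_full by hand
    g <- globalStats(em)
    ns <- normalizeTissue(em, "Tissue01")
    pk <- extractPeaks(ns)@peakValues
    want <- 1 / mean(pk)
    got <- sr@stats$lambda_full[sr@stats$tissue_id == "Tissue01"]
    expect_equal(got, want)
})

test_that("frozen globals with no removal give exact zeros everywhere", {
    em <- tinyMatrix(40, 5)
    cfg <- shiftConfig(freezeGlobals = TRUE, fitGamma = FALSE)
    sr <- computeShift(em, GeneSet("none", character()), config = cfg)
    expect_identical(unique(sr@stats$delta_lambda), 0)
    expect_identical(unique(sr@stats$emd), 0)
})

test_that("inflating the planted genes' expression increases the target
           tissue's shift", {
    set.seed(55)
    base <- matrix(rlnorm(300 * 6, 0, 1), 300, 6,
                   dimnames = list(sprintf("G%03d", 1:300),
                                   sprintf("Tissue%02d", 1:6)))
    dg <- sprintf("G%03d", 1:30)
    cfg <- shiftConfig(freezeGlobals = TRUE, fitGamma = FALSE)
    dOf <- function(fold) {
        m <- base
        m[dg, "Tissue03"] <- m[dg, "Tissue03"] * fold
        sr <- computeShift(TissueExpression(m), GeneSet("d", dg),
                           config = cfg)
        sr@stats$delta_lambda[sr@stats$tissue_id == "Tissue03"]
    }
    d <- vapply(c(1, 5, 25, 125), dOf, numeric(1))
    expect_true(all(diff(d) > 0))
})
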