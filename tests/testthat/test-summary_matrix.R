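mkShift <- function(disease, tissues, dl) {
    ord <- order(dl, tissues, method = "radix")
    n <- length(tissues)
    stats <- data.frame(tissue_id = tissues[ord],
                        lambda_full = 1, lambda_removed = 1 + dl[ord],
                        delta_lambda = dl[ord], emd = 0,
                        rank = seq_len(n),
                        block = rep(seq_len(2), partitionBlocks(n, 2)),
                        group = "peripheral_organ")
    new("ShiftResult", disease = disease, stats = stats, nBlocks = 2L)
}

test_that("summary rows normalize by their maximum and binarize strictly", {
    sr <- mkShift("d1", c("T1", "T2", "T3"), c(1, 2, 4))
    sm <- buildSummary(list(sr), threshold = 0.8)
    expect_identical(sm@diseaseIds, c("full_genome", "d1"))
    expect_equal(unname(sm@normValues["d1", c("T1", "T2", "T3")]),
                 c(0.25, 0.5, 1))
    expect_identical(unname(sm@binary["d1", c("T1", "T2", "T3")]),
                     c(FALSE, FALSE, TRUE))
    # reference row: all zeros, all OFF
    expect_true(all(sm@normValues["full_genome", ] == 0))
    expect_false(any(sm@binary["full_genome", ]))
    # exactly-at-threshold stays OFF (strict >)
    sr2 <- mkShift("d2", c("T1", "T2", "T3"), c(0.8, 0.5, 1))
    sm2 <- buildSummary(list(sr2), threshold = 0.8)
    expect_false(sm2@binary["d2", "T1"])
})

test_that("row count tracks the input and columns sort alphabetically", {
    tissues <- c("Zeta", "Alpha", "Mid")
    res <- lapply(1:26, function(i)
        mkShift(paste0("d", i), tissues, runif(3)))
    sm <- buildSummary(res)
    expect_identical(length(sm@diseaseIds), 27L)  # 26 diseases + reference
    expect_identical(sm@tissueIds, c("Alpha", "Mid", "Zeta"))
    bad <- mkShift("odd", c("Other", "Alpha", "Mid"), runif(3))
    expect_error(buildSummary(c(res, list(bad))), "same tissue set")
})

test_that("row normalization is scale invariant and all-zero rows warn", {
    tissues <- c("T1", "T2", "T3", "T4")
    dl <- c(0.1, 0.7, 0.3, 0.05)
    a <- buildSummary(list(mkShift("d", tissues, dl)))
    b <- buildSummary(list(mkShift("d", tissues, dl * 137.5)))
    expect_equal(a@normValues, b@normValues)
    expect_identical(a@binary, b@binary)
    expect_warning(z <- buildSummary(list(mkShift("flat", tissues,
                                                  rep(0, 4)))),
                   "all-zero")
    expect_true(all(z@normValues["flat", ] == 0))
})

test_that("binarization is monotone in the threshold", {
    tissues <- sprintf("T%02d", 1:10)
    sr <- mkShift("d", tissues, runif(10))
    on <- function(t) {
        sm <- buildSummary(list(sr), threshold = t)
        sm@tissueIds[sm@binary["d", ]]
    }
    for (pair in list(c(0.2, 0.5), c(0.5, 0.8), c(0.8, 0.95)))
        expect_true(all(on(pair[2]) %in% on(pair[1])))
})

test_that("overlap report intersects ON-sets across disease groups", {
    tissues <- c("Brain", "Heart", "Liver", "Muscle")
    r <- list(
        mkShift("mentalA", tissues, c(1.0, 0.9, 0.1, 0.2)),
        mkShift("mentalB", tissues, c(0.9, 1.0, 0.1, 0.2)),
        mkShift("cancerA", tissues, c(0.1, 0.95, 1.0, 0.2)),
        mkShift("cancerB", tissues, c(0.2, 1.0, 0.9, 0.1)))
    sm <- buildSummary(r, threshold = 0.8)
    rep <- overlapReport(sm, c("mentalA", "mentalB"),
                         c("cancerA", "cancerB"))
    expect_setequal(rep$commonA, c("Brain", "Heart"))
    expect_setequal(rep$commonB, c("Heart", "Liver"))
    expect_identical(rep$intersection, "Heart")
    expect_identical(rep$onlyA, "Brain")
    expect_identical(rep$onlyB, "Liver")
    # identical groups intersect to their own common set
    same <- overlapReport(sm, c("mentalA", "mentalB"),
                          c("mentalA", "mentalB"))
    expect_identical(same$intersection, same$commonA)
    expect_error(overlapReport(sm, "mentalA", "nope"), "unknown disease")
})

test_that("parameter-space points carry the closed-form gamma moments", {
    f1 <- new("GammaFit", tissueId = "T1", shape = 1, scale = 0.5,
              moments = gammaMoments(1, 0.5), nDropped = 0L)
    f2 <- new("GammaFit", tissueId = "T2", shape = 4, scale = 1,
              moments = gammaMoments(4, 1), nDropped = 0L)
    ps <- paramSpace(list(f1, f2), c(T1 = 0.3, T2 = 0.9))
    expect_equal(ps$mean, c(0.5, 4))
    expect_equal(ps$variance, c(0.25, 4))
    expect_equal(ps$skewness, c(2, 1))
    expect_equal(ps$kurtosis, c(6, 1.5))
    expect_equal(ps$color_value, c(0.3, 0.9))
    # recompute the formulas independently over random fits
    set.seed(4)
    for (rep in 1:10) {
        a <- runif(1, 0.2, 8); b <- runif(1, 0.1, 5)
        f <- new("GammaFit", tissueId = "X", shape = a, scale = b,
                 moments = gammaMoments(a, b), nDropped = 0L)
        p <- paramSpace(list(f), c(X = 1))
        expect_equal(c(p$mean, p$variance, p$skewness, p$kurtosis),
                     c(a * b, a * b^2, 2 / sqrt(a), 6 / a))
    }
    expect_error(paramSpace(list(f1), c(T9 = 1)), "no gamma fit")
})
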