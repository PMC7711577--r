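test_that("GCT files round-trip bit-exactly and enforce the format", {
    em <- tinyMatrix(3, 2)
    path <- withr::local_tempfile(fileext = ".gct")
    writeGCT(em, path)
    back <- readGCT(path)
    expect_identical(tpm(back), tpm(em))
    expect_identical(geneIds(back), geneIds(em))
    expect_identical(tissueIds(back), tissueIds(em))

    bad <- withr::local_tempfile(fileext = ".gct")
    writeLines(c("#1.3", "1\t1", "Name\tDescription\tT1", "A\tA\t1"), bad)
    expect_error(readGCT(bad), "version")

    neg <- withr::local_tempfile(fileext = ".gct")
    writeLines(c("#1.2", "1\t1", "Name\tDescription\tT1", "A\tA\t-3"), neg)
    expect_error(readGCT(neg), "negative")
})

test_that("duplicate gene symbols keep the first row with a warning", {
    path <- withr::local_tempfile(fileext = ".gct")
    writeLines(c("#1.2", "3\t2", "Name\tDescription\tT1\tT2",
                 "ENSG1\tfoo\t1\t2", "ENSG2\t foo \t3\t4",
                 "ENSG3\tbar\t5\t6"), path)
    expect_warning(em <- readGCT(path), "duplicate")
    expect_identical(geneIds(em), c("FOO", "BAR"))
    expect_equal(unname(tpm(em)["FOO", ]), c(1, 2))
})

test_that("symbols come from the Description column when present", {
    path <- withr::local_tempfile(fileext = ".gct")
    writeLines(c("#1.2", "2\t1", "Name\tDescription\tT1",
                 "ENSG0001.5\tshank3\t1", "ENSG0002.1\t\t2"), path)
    em <- readGCT(path)
    expect_identical(geneIds(em), c("SHANK3", "ENSG0002.1"))
})

test_that("gene-set files parse with canonicalization and deduplication", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,score", "shank3,1", "MECP2,2S", " shank3 ,3",
                 "FMR1,", "CNTNAP2,S"), path)
    gs <- readGeneSet(path, name = "autism_like")
    expect_length(genes(gs), 4)
    expect_setequal(genes(gs), c("SHANK3", "MECP2", "FMR1", "CNTNAP2"))
    expect_identical(unname(geneScores(gs)["SHANK3"]), "1")

    blank <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene", "", "  ", ""), blank)
    expect_error(readGeneSet(blank), "no gene symbols")
})

test_that("presence confirmation reports absentees and is idempotent", {
    em <- TissueExpression(matrix(1, 3, 2,
        dimnames = list(c("A", "C", "D"), c("T1", "T2"))))
    gs <- GeneSet("d", c("A", "B", "C"))
    r <- intersectWithMatrix(gs, em)
    expect_setequal(genes(r$geneSet), c("A", "C"))
    expect_identical(r$absent, "B")
    r2 <- intersectWithMatrix(r$geneSet, em)
    expect_identical(genes(r2$geneSet), genes(r$geneSet))
    expect_identical(r2$nAbsent, 0L)

    disjoint <- intersectWithMatrix(GeneSet("x", c("Q", "Z")), em)
    expect_length(genes(disjoint$geneSet), 0)
    expect_identical(disjoint$nAbsent, 2L)

    subset <- intersectWithMatrix(GeneSet("y", c("A", "D")), em)
    expect_identical(subset$absent, character(0))
})

test_that("gene-set intersection obeys the lattice bounds", {
    a <- GeneSet("a", c("A", "B", "C"), scores = c(A = "1", B = "2"))
    b <- GeneSet("b", c("B", "C", "D"))
    ab <- overlapGeneSets(a, b)
    expect_setequal(genes(ab), c("B", "C"))
    expect_identical(unname(geneScores(ab)["B"]), "2")
    expect_length(genes(overlapGeneSets(a, GeneSet("e", "Z"))), 0)
    # |a n b| <= min(|a|, |b|), equality iff containment
    set.seed(3)
    for (i in 1:20) {
        ga <- GeneSet("ga", sample(LETTERS, sample(3:10, 1)))
        gb <- GeneSet("gb", sample(LETTERS, sample(3:10, 1)))
        ov <- overlapGeneSets(ga, gb)
        expect_lte(length(genes(ov)),
                   min(length(genes(ga)), length(genes(gb))))
        expect_identical(length(genes(ov)) == length(genes(ga)),
                         all(genes(ga) %in% genes(gb)))
    }
})

test_that("submatrix extraction restricts rows and log-transforms", {
    em <- tinyMatrix(10, 4)
    gs <- GeneSet("d", geneIds(em)[c(2, 5, 7)])
    sub <- extractSubmatrix(em, gs)
    expect_identical(dim(sub), c(3L, 4L))

    m <- matrix(c(0, 99), 2, 1, dimnames = list(c("A", "B"), "T1"))
    lg <- extractSubmatrix(TissueExpression(m), GeneSet("d", c("A", "B")),
                           logTransform = TRUE)
    expect_equal(unname(tpm(lg)[, 1]), c(0, 2))
    expect_error(extractSubmatrix(em, GeneSet("none", "ZZZ")), "present")
})

test_that("matrices reject negative or non-finite values and bad ids", {
    expect_error(TissueExpression(matrix(-1, 1, 1,
        dimnames = list("A", "T"))), "non-negative")
    expect_error(TissueExpression(matrix(NA_real_, 1, 1,
        dimnames = list("A", "T"))), "finite")
    expect_error(TissueExpression(matrix(1, 1, 1)), "identifiers")
})

test_that("taxonomy patterns match in order with a peripheral fallback", {
    tax <- gtexTaxonomy()
    g <- assignGroups(tax, c("Brain - Cortex",
                             "Brain - Spinal cord (cervical c-1)",
                             "Heart - Left Ventricle", "Muscle - Skeletal",
                             "Pancreas", "Esophagus - Muscularis"))
    expect_identical(g, c("CNS", "CNS", "heart", "muscle_skeletal",
                          "peripheral_organ", "peripheral_organ"))
    noCatch <- TissueTaxonomy("brain", "CNS")
    expect_warning(g2 <- assignGroups(noCatch, c("Brain - Cortex", "Liver")),
                   "not matched")
    expect_identical(g2, c("CNS", "peripheral_organ"))
})

test_that("taxonomy files load from YAML and CSV", {
    yml <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("- pattern: brain", "  group: CNS",
                 "- pattern: ''", "  group: peripheral_organ"), yml)
    tax <- readTaxonomy(yml)
    expect_identical(assignGroups(tax, "Brain - Amygdala"), "CNS")
    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("pattern,group", "heart,heart", ",peripheral_organ"), csv)
    tax2 <- readTaxonomy(csv)
    expect_identical(assignGroups(tax2, c("Heart - Left Ventricle", "Lung")),
                     c("heart", "peripheral_organ"))
})
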