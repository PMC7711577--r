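#' Canonicalize gene symbols
#'
#' Upper-cases and strips surrounding whitespace so that symbols from
#' different sources (expression matrices, disease gene lists) compare
#' equal.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonicalizeSymbols <- function(x) toupper(trimws(as.character(x)))

#' Construct a TissueExpression object
#'
#' Wraps a non-negative gene x tissue TPM matrix. Gene identifiers are
#' canonicalized; duplicate symbols keep the first row with a warning.
#'
#' @param tpm numeric matrix, genes x tissues.
#' @param geneIds,tissueIds identifiers; default to the dimnames of `tpm`.
#' @return a [TissueExpression-class] object.
#' @examples
#' m <- matrix(c(0, 2, 4, 10, 1, 3), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("Liver", "Lung")))
#' TissueExpression(m)
#' @export
TissueExpression <- function(tpm, geneIds = rownames(tpm),
                             tissueIds = colnames(tpm)) {
    tpm <- as.matrix(tpm)
    storage.mode(tpm) <- "double"
    if (is.null(geneIds))
        stop("gene identifiers are required")
    if (is.null(tissueIds))
        stop("tissue identifiers are required")
    geneIds <- canonicalizeSymbols(geneIds)
    dup <- duplicated(geneIds)
    if (any(dup)) {
        warning(sum(dup), " duplicate gene symbol(s) after canonicalization; ",
                "keeping first occurrence: ",
                paste(utils::head(unique(geneIds[dup]), 5L), collapse = ", "))
        tpm <- tpm[!dup, , drop = FALSE]
        geneIds <- geneIds[!dup]
    }
    dimnames(tpm) <- list(geneIds, as.character(tissueIds))
    new("TissueExpression",
        SummarizedExperiment(assays = list(tpm = tpm)))
}

#' Construct a GeneSet
#'
#' @param name disease label.
#' @param genes character vector of gene symbols (canonicalized, duplicates
#'   collapsed keeping the first score).
#' @param scores optional named character vector of category labels, or an
#'   unnamed vector parallel to `genes`.
#' @return a [GeneSet-class] object.
#' @export
GeneSet <- function(name, genes, scores = NULL) {
    genes <- canonicalizeSymbols(genes)
    genes <- genes[nzchar(genes) & !is.na(genes)]
    if (is.null(scores)) {
        scores <- setNames(character(), character())
    } else {
        if (is.null(names(scores))) {
            if (length(scores) != length(genes))
                stop("unnamed 'scores' must be parallel to 'genes'")
            names(scores) <- genes
        } else {
            names(scores) <- canonicalizeSymbols(names(scores))
        }
        scores <- scores[!duplicated(names(scores))]
    }
    keep <- !duplicated(genes)
    genes <- genes[keep]
    scores <- scores[names(scores) %in% genes]
    new("GeneSet", setName = as.character(name), genes = genes,
        scores = setNames(as.character(scores), names(scores)))
}

#' Construct a TissueTaxonomy
#'
#' @param pattern character vector of case-insensitive substring patterns,
#'   evaluated in order (first match wins; `""` matches everything).
#' @param group character vector of group labels, one of `CNS`, `heart`,
#'   `muscle_skeletal`, `peripheral_organ`.
#' @return a [TissueTaxonomy-class] object.
#' @export
TissueTaxonomy <- function(pattern, group) {
    new("TissueTaxonomy",
        mapping = data.frame(pattern = as.character(pattern),
                             group = as.character(group)))
}

#' Built-in GTEx-style tissue taxonomy
#'
#' Brain and spinal-cord tissues map to `CNS`, heart tissues to `heart`,
#' skeletal muscle to `muscle_skeletal`, and everything else (via the
#' catch-all rule) to `peripheral_organ`.
#'
#' @return a [TissueTaxonomy-class] object.
#' @export
gtexTaxonomy <- function() {
    TissueTaxonomy(
        pattern = c("brain", "spinal", "heart", "muscle - skeletal", ""),
        group = c("CNS", "CNS", "heart", "muscle_skeletal",
                  "peripheral_organ"))
}

#' Assign taxonomy groups to tissues
#'
#' Patterns are matched case-insensitively as fixed substrings, in mapping
#' order; the first match wins. Tissues matching no rule fall back to
#' `peripheral_organ` with a warning.
#'
#' @param taxonomy a [TissueTaxonomy-class].
#' @param tissues character vector of tissue names.
#' @return character vector of group labels, one per tissue.
#' @export
assignGroups <- function(taxonomy, tissues) {
    stopifnot(is(taxonomy, "TissueTaxonomy"))
    low <- tolower(tissues)
    out <- rep(NA_character_, length(tissues))
    for (i in seq_len(nrow(taxonomy@mapping))) {
        pat <- tolower(taxonomy@mapping$pattern[i])
        hit <- is.na(out) & grepl(pat, low, fixed = TRUE)
        out[hit] <- taxonomy@mapping$group[i]
    }
    if (anyNA(out)) {
        warning("tissues not matched by any taxonomy rule, ",
                "assigned 'peripheral_organ': ",
                paste(tissues[is.na(out)], collapse = ", "))
        out[is.na(out)] <- "peripheral_organ"
    }
    out
}

#' Read a taxonomy mapping file
#'
#' Accepts YAML (a list of `pattern`/`group` entries) or CSV/TSV with
#' columns `pattern` and `group`.
#'
#' @param path file path, `.yaml`/`.yml` or `.csv`/`.tsv`.
#' @return a [TissueTaxonomy-class].
#' @export
readTaxonomy <- function(path) {
    if (!file.exists(path)) stop("taxonomy file not found: ", path)
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        y <- yaml::read_yaml(path)
        pat <- vapply(y, function(e) as.character(e$pattern), character(1))
        grp <- vapply(y, function(e) as.character(e$group), character(1))
        return(TissueTaxonomy(pat, grp))
    }
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    if (!all(c("pattern", "group") %in% names(d)))
        stop("taxonomy table needs columns 'pattern' and 'group'")
    TissueTaxonomy(d$pattern, d$group)
}

#' Read a GCT 1.2 expression file
#'
#' Parses the tab-separated GCT dialect: a `#1.2` version line, a
#' dimensions line, then a header `Name<tab>Description<tab><tissues...>`.
#' The gene symbol is taken from the `Description` column where non-empty
#' (GTEx files carry Ensembl IDs in `Name` and symbols in `Description`),
#' otherwise from `Name`. Duplicate symbols after canonicalization keep the
#' first row with a warning.
#'
#' @param path path to a GCT file.
#' @return a [TissueExpression-class].
#' @export
readGCT <- function(path) {
    if (!file.exists(path)) stop("GCT file not found: ", path)
    con <- file(path, "r")
    on.exit(close(con))
    version <- readLines(con, n = 1L)
    if (!identical(trimws(version), "#1.2"))
        stop("malformed GCT version line (expected '#1.2'): ", version)
    dims <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
        stop("malformed GCT dimensions line")
    nGenes <- as.integer(dims[1]); nTissues <- as.integer(dims[2])
    d <- read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
    if (ncol(d) != nTissues + 2L)
        stop("GCT column count disagrees with the dimensions line")
    if (nrow(d) != nGenes)
        stop("GCT row count disagrees with the dimensions line")
    sym <- ifelse(!is.na(d[[2]]) & nzchar(trimws(d[[2]])), d[[2]], d[[1]])
    vals <- as.matrix(d[, -(1:2), drop = FALSE])
    storage.mode(vals) <- "double"
    if (any(!is.finite(vals)))
        stop("GCT contains non-finite expression values")
    if (any(vals < 0))
        stop("GCT contains negative expression values")
    TissueExpression(vals, geneIds = sym, tissueIds = colnames(d)[-(1:2)])
}

#' Write a GCT 1.2 expression file
#'
#' Values are written with 17 significant digits so that
#' `readGCT(writeGCT(x))` round-trips bit-exactly.
#'
#' @param em a [TissueExpression-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGCT <- function(em, path) {
    stopifnot(is(em, "TissueExpression"))
    m <- tpm(em)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#1.2", con)
    writeLines(paste(nrow(m), ncol(m), sep = "\t"), con)
    writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"),
               con)
    body <- cbind(rownames(m), rownames(m),
                  matrix(sprintf("%.17g", m), nrow = nrow(m)))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read a disease gene-set file
#'
#' CSV or TSV with a header; a column named `gene` (case-insensitive) is
#' required and a `score` column is optional. Symbols are canonicalized,
#' blank rows skipped and duplicates collapsed (first score kept).
#'
#' @param path file path (`.tsv` implies tab-separated, otherwise comma).
#' @param name disease label; defaults to the file base name.
#' @return a [GeneSet-class].
#' @export
readGeneSet <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path)) stop("gene-set file not found: ", path)
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
    geneCol <- which(tolower(names(d)) == "gene")
    if (!length(geneCol))
        stop("gene-set file needs a 'gene' column: ", path)
    scoreCol <- which(tolower(names(d)) == "score")
    g <- d[[geneCol[1]]]
    keep <- !is.na(g) & nzchar(trimws(g))
    g <- g[keep]
    if (!length(g))
        stop("gene-set file contains no gene symbols: ", path)
    scores <- NULL
    if (length(scoreCol)) {
        scores <- as.character(d[[scoreCol[1]]])[keep]
        names(scores) <- canonicalizeSymbols(g)
        scores <- scores[!is.na(scores) & nzchar(scores)]
    }
    GeneSet(name, g, scores)
}

#' Confirm gene-set presence in an expression matrix
#'
#' Restricts a gene set to the symbols present in the matrix (genes must be
#' confirmed present before removal) and reports the absent symbols.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param gs a [GeneSet-class].
#' @param em a [TissueExpression-class].
#' @return list with elements `geneSet` (the restricted [GeneSet-class]),
#'   `absent` (character vector) and `nAbsent`.
#' @export
intersectWithMatrix <- function(gs, em) {
    stopifnot(is(gs, "GeneSet"), is(em, "TissueExpression"))
    present <- genes(gs) %in% geneIds(em)
    kept <- genes(gs)[present]
    sc <- geneScores(gs)
    sc <- sc[names(sc) %in% kept]
    list(geneSet = new("GeneSet", setName = gs@setName, genes = kept,
                       scores = sc),
         absent = genes(gs)[!present],
         nAbsent = sum(!present))
}

#' Intersect two gene sets
#'
#' Returns the shared symbols named `"a:b"`; scores from the first set are
#' preserved where available.
#'
#' @param a,b [GeneSet-class] objects.
#' @return a [GeneSet-class] of the common genes.
#' @export
overlapGeneSets <- function(a, b) {
    stopifnot(is(a, "GeneSet"), is(b, "GeneSet"))
    common <- intersect(genes(a), genes(b))
    sc <- geneScores(a)
    sc <- sc[names(sc) %in% common]
    new("GeneSet", setName = paste(a@setName, b@setName, sep = ":"),
        genes = common, scores = sc)
}

#' Extract the expression submatrix of a gene set
#'
#' Restricts the matrix rows to the genes of `gs` (which should already be
#' confirmed present via [intersectWithMatrix()]); optionally transforms
#' values to `log10(TPM + 1)` for display on a log scale.
#'
#' @param em a [TissueExpression-class].
#' @param gs a [GeneSet-class] of genes present in `em`.
#' @param logTransform if `TRUE`, return `log10(TPM + 1)` values.
#' @return a [TissueExpression-class] restricted to the set's genes.
#' @export
extractSubmatrix <- function(em, gs, logTransform = FALSE) {
    stopifnot(is(em, "TissueExpression"), is(gs, "GeneSet"))
    keep <- geneIds(em) %in% genes(gs)
    if (!any(keep))
        stop("no genes of the set are present in the matrix")
    sub <- em[keep, ]
    if (logTransform) {
        m <- log10(tpm(sub) + 1)
        sub <- TissueExpression(m)
    }
    sub
}
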