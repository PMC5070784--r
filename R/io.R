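#' @include AllClasses.R
NULL

# %.17g preserves doubles exactly across a write/read cycle
.writeTsv <- function(d, path) {
    d <- as.data.frame(d)
    for (j in seq_along(d))
        if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write the package's tabular formats
#'
#' TSV readers/writers for the expression study (samples x genes
#' expression table, sample metadata, gene annotation with 1-based TSS),
#' allele-specific count tables, result tables and the population panel
#' (panel table plus populations x 12 monthly climate table). All writers
#' round-trip: re-reading an output reproduces the in-memory values.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param exprPath,metaPath,genesPath paths of the expression matrix
#'   (first column \code{sample}, then one column per gene), the sample
#'   metadata (\code{sample}, \code{individual}, \code{condition}) and the
#'   gene annotation (\code{gene_id}, \code{chrom}, \code{tss}).
#' @return readers return the parsed object; writers return their path(s)
#'   invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeExpressionStudy <- function(study, exprPath, metaPath, genesPath) {
    m <- t(exprMatrix(study))
    .writeTsv(data.frame(sample = rownames(m), m, check.names = FALSE),
              exprPath)
    .writeTsv(as.data.frame(colData(study)), metaPath)
    g <- rowRanges(study)
    .writeTsv(data.frame(gene_id = names(g),
                         chrom = as.character(seqnames(g)),
                         tss = start(g)), genesPath)
    invisible(c(exprPath, metaPath, genesPath))
}

#' @rdname tableIO
#' @export
readExpressionStudy <- function(exprPath, metaPath, genesPath) {
    e <- .readTsv(exprPath)
    meta <- .readTsv(metaPath)
    g <- .readTsv(genesPath)
    m <- t(as.matrix(e[, -1, drop = FALSE]))
    colnames(m) <- e$sample
    genes <- GRanges(g$chrom, IRanges(g$tss, width = 1L))
    names(genes) <- g$gene_id
    ExpressionStudy(m[g$gene_id, , drop = FALSE], genes,
                    meta[match(colnames(m), meta$sample), ],
                    valueScale = "raw")
}

#' @rdname tableIO
#' @param ase allele-specific count table
#'   (see \code{\link{simulateAseCounts}}).
#' @param path file path.
#' @export
writeAseCounts <- function(ase, path) .writeTsv(ase, path)

#' @rdname tableIO
#' @export
readAseCounts <- function(path) .readTsv(path)

#' @rdname tableIO
#' @param panel a \linkS4class{PopulationPanel}.
#' @param panelPath,climatePath,backgroundPath paths for the population
#'   table, the monthly climate table and the background frequency table.
#' @export
writePopulationPanel <- function(panel, panelPath, climatePath,
                                 backgroundPath) {
    .writeTsv(panelPopulations(panel), panelPath)
    cl <- panelClimate(panel)
    .writeTsv(data.frame(population = rownames(cl), cl,
                         check.names = FALSE), climatePath)
    bg <- panelBackground(panel)
    .writeTsv(data.frame(snp = rownames(bg), bg, check.names = FALSE),
              backgroundPath)
    invisible(c(panelPath, climatePath, backgroundPath))
}

#' @rdname tableIO
#' @export
readPopulationPanel <- function(panelPath, climatePath, backgroundPath) {
    pops <- .readTsv(panelPath)
    cl <- .readTsv(climatePath)
    climate <- as.matrix(cl[, -1, drop = FALSE])
    rownames(climate) <- cl$population
    bg <- .readTsv(backgroundPath)
    background <- as.matrix(bg[, -1, drop = FALSE])
    rownames(background) <- bg$snp
    new("PopulationPanel", populations = pops,
        background = background[, pops$population, drop = FALSE],
        climate = climate[pops$population, , drop = FALSE])
}
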