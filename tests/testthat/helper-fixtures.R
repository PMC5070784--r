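# Hand-built miniature objects used across test files.

makeGenotypes <- function(hap1, hap2, pos, chrom = "chr1",
                          ref = NULL, alt = NULL, gene = NULL,
                          causal = NULL, tss = 2e6) {
    n <- nrow(hap1)
    s <- ncol(hap1)
    snps <- GenomicRanges::GRanges(
        rep(chrom, length.out = s),
        IRanges::IRanges(start = pos, width = 1L),
        ref = if (is.null(ref)) rep("A", s) else ref,
        alt = if (is.null(alt)) rep("G", s) else alt,
        gene = if (is.null(gene)) rep("g1", s) else gene,
        causal = if (is.null(causal)) rep(FALSE, s) else causal)
    names(snps) <- sprintf("s%d", seq_len(s))
    genes <- GenomicRanges::GRanges(
        unique(chrom), IRanges::IRanges(start = tss, width = 1L))
    names(genes) <- unique(if (is.null(gene)) "g1" else gene)
    GenotypeMatrix(individuals = sprintf("i%d", seq_len(n)),
                   snps = snps, genes = genes, hap1 = hap1, hap2 = hap2)
}

makeStudy <- function(expr, individual, condition, chrom = "chr1",
                      tss = 2e6, valueScale = "raw") {
    genes <- GenomicRanges::GRanges(
        rep(chrom, length.out = nrow(expr)),
        IRanges::IRanges(start = rep(tss, length.out = nrow(expr)),
                         width = 1L))
    names(genes) <- rownames(expr)
    ExpressionStudy(expr, genes,
                    data.frame(sample = paste(individual, condition,
                                              sep = "-"),
                               individual = individual,
                               condition = condition),
                    valueScale = valueScale)
}

# condition-specific correlations at each gene's causal SNP, computed
# directly from the matrices (oracle-side helper)
condCor <- function(study, genotypes) {
    y <- log(exprMatrix(study))
    info <- SummarizedExperiment::colData(study)
    dos <- dosages(genotypes)
    rownames(dos) <- individuals(genotypes)
    cs <- causalSnps(genotypes)[rownames(y)]
    out <- lapply(seq_len(nrow(y)), function(g) {
        d <- dos[info$individual, cs[g]]
        se <- info$condition == "SE"
        data.frame(rSe = cor(d[se], y[g, se]),
                   rNse = cor(d[!se], y[g, !se]),
                   nSe = sum(se), nNse = sum(!se))
    })
    do.call(rbind, out)
}
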