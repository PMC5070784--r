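#' @include AllClasses.R
NULL

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits a plain-text VCF with phased GT genotypes (\code{h1|h2},
#' \code{./.} for missing), 1-based positions, one contig line per
#' chromosome, and the owning gene / causal designation of simulated SNPs
#' in the INFO field (\code{GENE=...;CAUSAL}).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(genotypes, path) {
    snps <- snpRanges(genotypes)
    hap <- haplotypes(genotypes)
    gt <- matrix("./.", length(snps), length(individuals(genotypes)))
    ok <- !is.na(t(hap$hap1)) & !is.na(t(hap$hap2))
    gt[ok] <- paste0(t(hap$hap1)[ok], "|", t(hap$hap2)[ok])
    mc <- mcols(snps)
    info <- rep(".", length(snps))
    hasGene <- !is.na(mc$gene)
    info[hasGene] <- paste0("GENE=", mc$gene[hasGene],
                            ifelse(mc$causal[hasGene], ";CAUSAL", ""))
    chroms <- unique(as.character(seqnames(snps)))
    header <- c("##fileformat=VCFv4.2",
                "##source=exposeQTL",
                paste0("##contig=<ID=", chroms, ">"),
                "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Owning gene\">",
                "##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description=\"Simulated causal SNP\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        individuals(genotypes)), collapse = "\t"))
    body <- paste(as.character(seqnames(snps)), start(snps), names(snps),
                  mc$ref, mc$alt, ".", "PASS", info, "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read phased genotypes from a VCF file
#'
#' Parses a VCF v4.x file with a GT FORMAT field into a
#' \linkS4class{GenotypeMatrix}. Multi-allelic records are skipped (with a
#' message giving the count); \code{./.} yields missing haplotypes for
#' that individual at that SNP, handled pairwise-complete downstream. By
#' default unphased heterozygous calls (\code{0/1}) are an error because
#' the ASE stages need phase; with \code{requirePhased = FALSE} they are
#' accepted with arbitrary haplotype order.
#'
#' @param path VCF file path.
#' @param requirePhased error on unphased heterozygous GT (default TRUE).
#' @return A \linkS4class{GenotypeMatrix}; MAF is computed from the
#'   parsed dosages. If the file was written by
#'   \code{\link{writeGenotypeVcf}}, gene/causal annotations are
#'   recovered from INFO.
#' @export
readGenotypeVcf <- function(path, requirePhased = TRUE) {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (length(hdr) != 1)
        stop("malformed VCF: no #CHROM header line in ", path)
    cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 10)
        stop("VCF has no sample columns")
    ind <- cols[-(1:9)]
    body <- lines[-seq_len(hdr)]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(cols)))
        stop("malformed VCF record at line ",
             hdr + which(nf != length(cols))[1])
    rec <- do.call(rbind, fields)
    multi <- grepl(",", rec[, 5], fixed = TRUE)
    if (any(multi))
        message("skipped ", sum(multi), " multi-allelic record(s)")
    rec <- rec[!multi, , drop = FALSE]
    if (nrow(rec) == 0) stop("no biallelic records in ", path)

    gtIdx <- vapply(strsplit(rec[, 9], ":", fixed = TRUE),
                    function(f) match("GT", f), integer(1))
    if (anyNA(gtIdx)) stop("record without GT in FORMAT")
    nSnp <- nrow(rec)
    h1 <- h2 <- matrix(NA_real_, length(ind), nSnp)
    for (s in seq_len(nSnp)) {
        gt <- vapply(strsplit(rec[s, -(1:9)], ":", fixed = TRUE),
                     `[`, character(1), gtIdx[s])
        miss <- gt %in% c("./.", ".|.", ".")
        phased <- grepl("|", gt, fixed = TRUE)
        al <- matrix(NA_real_, length(ind), 2)
        parse <- !miss
        sp <- strsplit(gt[parse], "[|/]")
        if (any(lengths(sp) != 2))
            stop("unparseable GT at record ", s)
        al[parse, ] <- matrix(as.numeric(unlist(sp)), ncol = 2,
                              byrow = TRUE)
        het <- parse & !phased & al[, 1] != al[, 2]
        if (requirePhased && any(het))
            stop("unphased heterozygous GT at record ", s,
                 " (phase required for ASE stages; ",
                 "use requirePhased = FALSE to accept)")
        h1[, s] <- al[, 1]
        h2[, s] <- al[, 2]
    }
    storage.mode(h1) <- storage.mode(h2) <- "integer"
    ids <- rec[, 3]
    blank <- ids == "."
    ids[blank] <- paste0(rec[blank, 1], ":", rec[blank, 2])
    gene <- rep(NA_character_, nSnp)
    hasGene <- grepl("GENE=", rec[, 8], fixed = TRUE)
    gene[hasGene] <- sub(".*GENE=([^;]+).*", "\\1", rec[hasGene, 8])
    snps <- GRanges(rec[, 1], IRanges(as.integer(rec[, 2]), width = 1L),
                    ref = rec[, 4], alt = rec[, 5], gene = gene,
                    causal = grepl("CAUSAL", rec[, 8], fixed = TRUE))
    names(snps) <- ids
    GenotypeMatrix(individuals = ind, snps = snps, hap1 = h1, hap2 = h2)
}
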