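#' @include AllClasses.R
NULL

#' Accessors for the package's data classes
#'
#' @param x a \linkS4class{GenotypeMatrix}, \linkS4class{ExpressionStudy},
#'   \linkS4class{FoldChangeMatrix} or \linkS4class{PopulationPanel}.
#' @return \code{individuals}: character vector of individual ids.
#'   \code{dosages}: numeric individuals x SNPs matrix in \{0,1,2\}.
#'   \code{haplotypes}: list with 0/1 matrices \code{hap1}, \code{hap2}.
#'   \code{snpRanges}, \code{geneRanges}: \code{GRanges}.
#'   \code{causalSnps}: named character vector, gene id -> causal SNP id.
#'   \code{exprMatrix}: genes x samples matrix. \code{sampleInfo}:
#'   \code{DataFrame} of sample metadata. \code{fcValues},
#'   \code{fcZeroFlags}: individuals x genes matrices.
#'   \code{panelPopulations}: data.frame; \code{panelBackground},
#'   \code{panelClimate}: matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("causalSnps", function(x) standardGeneric("causalSnps"))
#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("fcZeroFlags", function(x) standardGeneric("fcZeroFlags"))
#' @rdname accessors
#' @export
setGeneric("panelPopulations", function(x) standardGeneric("panelPopulations"))
#' @rdname accessors
#' @export
setGeneric("panelBackground", function(x) standardGeneric("panelBackground"))
#' @rdname accessors
#' @export
setGeneric("panelClimate", function(x) standardGeneric("panelClimate"))

#' @rdname accessors
#' @export
setMethod("individuals", "GenotypeMatrix", function(x) x@individuals)
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@hap1 + x@hap2)
#' @rdname accessors
#' @export
setMethod("haplotypes", "GenotypeMatrix",
    function(x) list(hap1 = x@hap1, hap2 = x@hap2))
#' @rdname accessors
#' @export
setMethod("snpRanges", "GenotypeMatrix", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("geneRanges", "GenotypeMatrix", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("causalSnps", "GenotypeMatrix", function(x) {
    mc <- mcols(x@snps)
    keep <- which(mc$causal)
    structure(names(x@snps)[keep], names = mc$gene[keep])
})
#' @rdname accessors
#' @export
setMethod("exprMatrix", "ExpressionStudy", function(x) assay(x, "expr"))
#' @rdname accessors
#' @export
setMethod("sampleInfo", "ExpressionStudy", function(x) colData(x))
#' @rdname accessors
#' @export
setMethod("individuals", "ExpressionStudy",
    function(x) unique(colData(x)$individual))
#' @rdname accessors
#' @export
setMethod("geneRanges", "ExpressionStudy", function(x) rowRanges(x))
#' @rdname accessors
#' @export
setMethod("fcValues", "FoldChangeMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fcZeroFlags", "FoldChangeMatrix", function(x) x@zeroFlag)
#' @rdname accessors
#' @export
setMethod("individuals", "FoldChangeMatrix",
    function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("geneRanges", "FoldChangeMatrix", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("panelPopulations", "PopulationPanel", function(x) x@populations)
#' @rdname accessors
#' @export
setMethod("panelBackground", "PopulationPanel", function(x) x@background)
#' @rdname accessors
#' @export
setMethod("panelClimate", "PopulationPanel", function(x) x@climate)

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d individuals, %d genes, %d SNPs/gene, MAF in [%g, %g]\n",
        object@nIndividuals, object@nGenes, object@nSnpsPerGene,
        object@mafRange[1], object@mafRange[2]))
    cat(sprintf("  cis effect: beta_SE = %g, beta_NSE = %g (latent log scale)\n",
        object@betaSe, object@betaNse))
    cat(sprintf("  noise sd %g, individual sd %g; ASE depth %g, rho %g\n",
        object@noiseSd, object@individualSd, object@aseDepthMean,
        object@aseOverdispersion))
    cat(sprintf("  paired fraction %g, phase error %g, seed %d\n",
        object@pairedFraction, object@phaseError, object@seed))
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%d genes)\n",
        length(object@individuals), length(object@snps),
        length(object@genes)))
    if (length(object@snps))
        cat(sprintf("  MAF range [%.3f, %.3f]; %d causal SNP(s)\n",
            min(mcols(object@snps)$maf), max(mcols(object@snps)$maf),
            sum(mcols(object@snps)$causal)))
})

setMethod("show", "FoldChangeMatrix", function(object) {
    cat(sprintf(
        "FoldChangeMatrix: %d paired individuals x %d genes (%d zero-substituted cells)\n",
        nrow(object@values), ncol(object@values), sum(object@zeroFlag)))
})

setMethod("show", "PopulationPanel", function(object) {
    cat(sprintf(
        "PopulationPanel: %d populations in %d regional groups; %d background SNPs\n",
        nrow(object@populations), length(unique(object@populations$group)),
        nrow(object@background)))
})
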