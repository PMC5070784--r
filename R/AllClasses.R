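#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges
NULL

#' Simulation settings for a paired-condition cis-regulation study
#'
#' Holds every tunable of the synthetic-data generators: study dimensions,
#' the additive cis effect of the causal allele in each exposure condition
#' (on the latent log-expression scale, in s.d. units per allele), noise and
#' shared-individual variance components, the allele-specific read-depth
#' model, and the random seed from which all generators derive their
#' randomness.
#'
#' @slot nIndividuals number of genotyped individuals.
#' @slot nGenes number of genes.
#' @slot nSnpsPerGene local SNPs simulated per gene (one designated causal).
#' @slot mafRange allele-frequency range, both ends in (0, 0.5].
#' @slot betaSe,betaNse additive cis effect per causal allele on latent
#'   log expression, in the SE (exposed) and NSE (unexposed) condition.
#' @slot noiseSd residual s.d. of latent log expression.
#' @slot individualSd s.d. of the per-individual random effect shared by
#'   both conditions of the same donor.
#' @slot aseDepthMean mean Poisson read depth per gene-sample for the
#'   allele-specific counts.
#' @slot aseOverdispersion beta-binomial overdispersion rho in [0, 1);
#'   0 gives plain binomial sampling.
#' @slot pairedFraction fraction of individuals sampled in both conditions.
#' @slot phaseError probability that the phase of an allele-specific count
#'   record is flipped relative to the eQTL (switch error).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nIndividuals = "integer",
    nGenes = "integer",
    nSnpsPerGene = "integer",
    mafRange = "numeric",
    betaSe = "numeric",
    betaNse = "numeric",
    noiseSd = "numeric",
    individualSd = "numeric",
    aseDepthMean = "numeric",
    aseOverdispersion = "numeric",
    pairedFraction = "numeric",
    phaseError = "numeric",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    bad <- function(field, msg) sprintf("invalid '%s': %s", field, msg)
    msgs <- character(0)
    for (f in c("nIndividuals", "nGenes", "nSnpsPerGene")) {
        v <- slot(object, f)
        if (length(v) != 1L || is.na(v) || v < 1L)
            msgs <- c(msgs, bad(f, "must be a count >= 1"))
    }
    mr <- object@mafRange
    if (length(mr) != 2L || any(is.na(mr)) || any(mr <= 0) ||
        any(mr > 0.5) || mr[1] > mr[2])
        msgs <- c(msgs, bad("mafRange", "must be within (0, 0.5], low <= high"))
    if (object@noiseSd < 0) msgs <- c(msgs, bad("noiseSd", "must be >= 0"))
    if (object@individualSd < 0)
        msgs <- c(msgs, bad("individualSd", "must be >= 0"))
    if (object@aseDepthMean < 0)
        msgs <- c(msgs, bad("aseDepthMean", "must be >= 0"))
    if (object@aseOverdispersion < 0 || object@aseOverdispersion >= 1)
        msgs <- c(msgs, bad("aseOverdispersion", "must be in [0, 1)"))
    if (object@pairedFraction <= 0 || object@pairedFraction > 1)
        msgs <- c(msgs, bad("pairedFraction", "must be in (0, 1]"))
    if (object@phaseError < 0 || object@phaseError > 0.5)
        msgs <- c(msgs, bad("phaseError", "must be in [0, 0.5]"))
    if (length(msgs)) msgs else TRUE
})

#' Construct a \linkS4class{SimulationConfig}
#'
#' Defaults describe the paired skin study the package emulates: 150
#' genotyped donors all sampled in both the sun-exposed (SE) and
#' non-sun-exposed (NSE) condition, an SE-specific cis effect of 0.8 latent
#' s.d. per allele, and allele-specific coverage of 50 reads per
#' gene-sample. See the package vignette for the rationale behind each
#' default.
#'
#' @param nIndividuals,nGenes,nSnpsPerGene study dimensions.
#' @param mafRange length-2 numeric, allele frequencies drawn uniformly
#'   from this interval.
#' @param betaSe,betaNse condition-specific additive cis effects.
#' @param noiseSd,individualSd latent-scale variance components.
#' @param aseDepthMean,aseOverdispersion allele-specific count model.
#' @param pairedFraction fraction of donors with both conditions.
#' @param phaseError switch-error rate of the ASE phasing.
#' @param seed integer seed; all four generators are deterministic given it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nIndividuals = 20, nGenes = 5, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(nIndividuals = 150L, nGenes = 200L,
                             nSnpsPerGene = 5L, mafRange = c(0.1, 0.5),
                             betaSe = 0.8, betaNse = 0, noiseSd = 0.5,
                             individualSd = 0.5, aseDepthMean = 50,
                             aseOverdispersion = 0.05, pairedFraction = 1,
                             phaseError = 0, seed = 1L) {
    new("SimulationConfig",
        nIndividuals = as.integer(nIndividuals),
        nGenes = as.integer(nGenes),
        nSnpsPerGene = as.integer(nSnpsPerGene),
        mafRange = as.numeric(mafRange),
        betaSe = as.numeric(betaSe), betaNse = as.numeric(betaNse),
        noiseSd = as.numeric(noiseSd),
        individualSd = as.numeric(individualSd),
        aseDepthMean = as.numeric(aseDepthMean),
        aseOverdispersion = as.numeric(aseOverdispersion),
        pairedFraction = as.numeric(pairedFraction),
        phaseError = as.numeric(phaseError),
        seed = as.integer(seed))
}

#' Phased genotypes with genomic coordinates
#'
#' Per-individual allele dosages in \{0, 1, 2\} together with the two
#' phased haplotypes they sum from, SNP coordinates and alleles as a
#' \link[GenomicRanges]{GRanges}, and the transcription start sites of the
#' genes whose cis windows the SNPs populate. Dosage counts the ALT allele.
#'
#' @slot individuals character vector of individual ids (dosage row names).
#' @slot snps GRanges of SNPs, names are SNP ids; metadata columns
#'   \code{ref}, \code{alt}, \code{maf}, \code{gene} (owning gene for
#'   simulated data, NA otherwise) and \code{causal}.
#' @slot genes GRanges of gene TSS positions, names are gene ids.
#' @slot hap1,hap2 0/1 matrices, individuals x SNPs; NA for missing calls.
#' @export
setClass("GenotypeMatrix", representation(
    individuals = "character",
    snps = "GRanges",
    genes = "GRanges",
    hap1 = "matrix",
    hap2 = "matrix"
))

setValidity("GenotypeMatrix", function(object) {
    msgs <- character(0)
    n <- length(object@individuals)
    s <- length(object@snps)
    for (h in c("hap1", "hap2")) {
        m <- slot(object, h)
        if (!identical(dim(m), c(n, s)))
            msgs <- c(msgs, sprintf("%s must be %d x %d", h, n, s))
        if (!all(m %in% c(0, 1) | is.na(m)))
            msgs <- c(msgs, sprintf("%s entries must be 0/1 or NA", h))
    }
    need <- c("ref", "alt", "maf")
    if (!all(need %in% names(mcols(object@snps))))
        msgs <- c(msgs, "snps must carry mcols ref, alt, maf")
    if (is.null(names(object@snps)) && s > 0)
        msgs <- c(msgs, "snps must be named by SNP id")
    if (!length(msgs) && n > 0 && s > 0) {
        dos <- object@hap1 + object@hap2
        af <- colMeans(dos, na.rm = TRUE) / 2
        maf <- pmin(af, 1 - af)
        tol <- 1 / (2 * n) + 1e-9
        off <- abs(maf - mcols(object@snps)$maf) > tol
        off[is.na(off)] <- FALSE
        if (any(off))
            msgs <- c(msgs, sprintf(
                "stored MAF disagrees with dosages beyond 1/(2n) at %d SNP(s)",
                sum(off)))
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn GenotypeMatrix-class constructor; \code{dosage} is derived
#'   as \code{hap1 + hap2} and MAF is recomputed when not supplied.
#' @param individuals,snps,genes,hap1,hap2 slot values (see slots).
#' @export
GenotypeMatrix <- function(individuals, snps, genes = GRanges(),
                           hap1, hap2) {
    dimnames(hap1) <- dimnames(hap2) <-
        list(individuals, names(snps))
    if (!"maf" %in% names(mcols(snps))) {
        af <- colMeans(hap1 + hap2, na.rm = TRUE) / 2
        mcols(snps)$maf <- pmin(af, 1 - af)
    }
    if (!"gene" %in% names(mcols(snps)))
        mcols(snps)$gene <- NA_character_
    if (!"causal" %in% names(mcols(snps)))
        mcols(snps)$causal <- FALSE
    new("GenotypeMatrix", individuals = as.character(individuals),
        snps = snps, genes = genes, hap1 = hap1, hap2 = hap2)
}

#' Paired-condition expression study
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} with genes in
#' rows (ranges give the TSS), samples in columns, and column metadata
#' mapping each sample to its donor (\code{individual}) and exposure
#' condition (\code{condition}, \code{"SE"} or \code{"NSE"}). The single
#' assay \code{"expr"} holds expression values; \code{metadata()$valueScale}
#' records whether they are \code{"raw"} (nonnegative, RPKM-like),
#' \code{"log"} or \code{"residual"}.
#'
#' @export
setClass("ExpressionStudy", contains = "RangedSummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
    msgs <- character(0)
    cd <- colData(object)
    if (!all(c("individual", "condition") %in% names(cd)))
        return("colData must contain 'individual' and 'condition'")
    if (!all(cd$condition %in% c("SE", "NSE")))
        msgs <- c(msgs, "condition must be 'SE' or 'NSE'")
    key <- paste(cd$individual, cd$condition)
    if (anyDuplicated(key))
        msgs <- c(msgs, "at most one sample per (individual, condition)")
    scale <- metadata(object)$valueScale
    if (is.null(scale)) scale <- "raw"
    if (identical(scale, "raw")) {
        m <- assay(object)
        if (any(m < 0, na.rm = TRUE))
            msgs <- c(msgs, "raw expression values must be nonnegative")
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn ExpressionStudy-class constructor.
#' @param expr numeric matrix, genes x samples.
#' @param genes GRanges of gene TSS positions, names matching rownames(expr).
#' @param sampleData data.frame with columns \code{sample},
#'   \code{individual}, \code{condition}, one row per column of \code{expr}.
#' @param valueScale one of \code{"raw"}, \code{"log"}, \code{"residual"}.
#' @export
ExpressionStudy <- function(expr, genes, sampleData,
                            valueScale = c("raw", "log", "residual")) {
    valueScale <- match.arg(valueScale)
    stopifnot(ncol(expr) == nrow(sampleData))
    cd <- DataFrame(sampleData)
    rownames(cd) <- sampleData$sample
    colnames(expr) <- sampleData$sample
    se <- SummarizedExperiment(
        assays = list(expr = expr),
        rowRanges = genes[rownames(expr)],
        colData = cd)
    metadata(se)$valueScale <- valueScale
    new("ExpressionStudy", se)
}

#' Within-individual fold-change matrix
#'
#' Transformed log fold changes (SE / NSE) for the individuals sampled in
#' both conditions. After the rank-based inverse-normal step every gene
#' column is marginally standard normal. \code{zeroFlag} records the cells
#' in which a zero expression value was replaced by the gene's minimum
#' nonzero value before the ratio was taken.
#'
#' @slot values numeric matrix, individuals x genes.
#' @slot zeroFlag logical matrix of the same shape.
#' @slot genes GRanges of the retained genes' TSS positions.
#' @export
setClass("FoldChangeMatrix", representation(
    values = "matrix",
    zeroFlag = "matrix",
    genes = "GRanges"
))

setValidity("FoldChangeMatrix", function(object) {
    msgs <- character(0)
    if (!identical(dim(object@values), dim(object@zeroFlag)))
        msgs <- c(msgs, "values and zeroFlag must have identical shape")
    if (ncol(object@values) != length(object@genes))
        msgs <- c(msgs, "one gene range per column required")
    if (ncol(object@values) > 0 &&
        max(abs(colMeans(object@values))) > 1e-8)
        msgs <- c(msgs, "gene columns must be centered (rankit transformed)")
    if (length(msgs)) msgs else TRUE
})

#' Population allele-frequency panel with environmental covariates
#'
#' Per-population allele frequency of a focal SNP together with a table of
#' background (putatively neutral) SNP frequencies, geographic coordinates,
#' regional group labels, sample sizes, and a 12-column matrix of monthly
#' environmental values (e.g. downward short-wave radiation flux, W m^-2;
#' January is column 1).
#'
#' @slot populations data.frame with columns \code{population},
#'   \code{group}, \code{latitude}, \code{longitude}, \code{n},
#'   \code{freq}.
#' @slot background numeric matrix, background SNPs x populations,
#'   frequencies in [0, 1].
#' @slot climate numeric matrix, populations x 12 monthly values.
#' @export
setClass("PopulationPanel", representation(
    populations = "data.frame",
    background = "matrix",
    climate = "matrix"
))

setValidity("PopulationPanel", function(object) {
    msgs <- character(0)
    pop <- object@populations
    need <- c("population", "group", "latitude", "longitude", "n", "freq")
    if (!all(need %in% names(pop)))
        return(paste("populations must contain:", paste(need, collapse = ", ")))
    if (anyDuplicated(pop$population))
        msgs <- c(msgs, "duplicate population ids")
    if (any(pop$freq < 0 | pop$freq > 1, na.rm = TRUE))
        msgs <- c(msgs, "frequencies must lie in [0, 1]")
    if (nrow(object@background) > 0 &&
        ncol(object@background) != nrow(pop))
        msgs <- c(msgs, "background must have one column per population")
    if (any(object@background < 0 | object@background > 1, na.rm = TRUE))
        msgs <- c(msgs, "background frequencies must lie in [0, 1]")
    if (nrow(object@climate) > 0 &&
        (nrow(object@climate) != nrow(pop) || ncol(object@climate) != 12L))
        msgs <- c(msgs, "climate must be populations x 12")
    if (length(msgs)) msgs else TRUE
})
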