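#' @include AllClasses.R simulate.R eqtl.R ase.R combine.R
NULL

# Columnwise correlation of two conformable matrices.
.colCor <- function(A, B) {
    A <- scale(A)
    B <- scale(B)
    colSums(A * B) / (nrow(A) - 1)
}

# Condition-specific Pearson correlations at each gene's causal SNP,
# computed vectorized over genes (each simulated gene is an independent
# replicate of the same study design).
.condCorAtCausal <- function(study, genotypes) {
    info <- colData(study)
    y <- t(base::log(exprMatrix(study)))        # samples x genes
    dos <- dosages(genotypes)
    rownames(dos) <- individuals(genotypes)
    cs <- causalSnps(genotypes)[colnames(y)]
    D <- dos[info$individual, cs, drop = FALSE]
    se <- info$condition == "SE"
    data.frame(gene = colnames(y),
               rSe = .colCor(D[se, , drop = FALSE],
                             y[se, , drop = FALSE]),
               rNse = .colCor(D[!se, , drop = FALSE],
                              y[!se, , drop = FALSE]),
               nSe = sum(se), nNse = sum(!se),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Type-I-error calibration of the effect-size test
#'
#' Simulates \code{nReps} independent genes under the shared-effect null
#' (the causal SNP has the same effect \code{beta} in both conditions)
#' and applies the effect-size test to each. The design is
#' between-individual — distinct donors contribute the SE and NSE
#' samples — because the test models the two correlations as independent;
#' see the vignette for why a strongly paired design with a large shared
#' donor effect makes the test conservative instead.
#'
#' @param nReps number of simulated genes (replicates).
#' @param nPerCondition donors per condition.
#' @param beta shared cis effect under the null.
#' @param noiseSd,individualSd variance components of the generator.
#' @param seed integer seed.
#' @return list with \code{p} (vector of p-values),
#'   \code{rejectionRate} at \eqn{\alpha = 0.05} and \code{ksP}, the
#'   Kolmogorov-Smirnov p-value against Uniform(0, 1).
#' @export
calibrateEffectSizeTest <- function(nReps = 10000L, nPerCondition = 150L,
                                    beta = 0.5, noiseSd = 0.5,
                                    individualSd = 0.5, seed = 1L) {
    cfg <- SimulationConfig(
        nIndividuals = 2L * nPerCondition, nGenes = as.integer(nReps),
        nSnpsPerGene = 1L, betaSe = beta, betaNse = beta,
        noiseSd = noiseSd, individualSd = individualSd,
        pairedFraction = 1 / (2 * nPerCondition), seed = seed)
    gm <- simulateGenotypes(cfg)
    st <- simulateExpression(gm, cfg)
    cc <- .condCorAtCausal(st, gm)
    es <- effectSizeTest(cc$rSe, cc$rNse, cc$nSe, cc$nNse)
    list(p = es$p, rejectionRate = mean(es$p < 0.05),
         ksP = suppressWarnings(
             stats::ks.test(es$p, "punif"))$p.value)
}

#' Joint behaviour of the effect-size and differential-ASE tests
#'
#' Simulates \code{nReps} genes in one paired study and computes, per
#' gene, both the effect-size p-value (at the causal SNP) and the
#' differential-ASE p-value. Under a null with no exposure-specific
#' effect the two p-values should be uncorrelated (the tests draw on
#' across- vs within-individual contrasts); in the presence of an
#' exposure-specific eQTL both respond to the same signal and correlate
#' positively, which is what licenses using one to validate the other.
#'
#' @param nReps number of simulated genes.
#' @param betaSe,betaNse condition-specific effects (equal values give
#'   the null).
#' @param nIndividuals paired donors.
#' @param aseDepthMean mean allele-specific read depth.
#' @param seed integer seed.
#' @return data.frame with one row per testable gene: \code{gene},
#'   \code{pEffectSize}, \code{pDiffAse}.
#' @export
testIndependenceExperiment <- function(nReps = 1000L, betaSe = 0.5,
                                       betaNse = 0.5,
                                       nIndividuals = 100L,
                                       aseDepthMean = 30, seed = 1L) {
    cfg <- SimulationConfig(
        nIndividuals = as.integer(nIndividuals),
        nGenes = as.integer(nReps), nSnpsPerGene = 1L,
        betaSe = betaSe, betaNse = betaNse,
        aseDepthMean = aseDepthMean, seed = seed)
    gm <- simulateGenotypes(cfg)
    st <- simulateExpression(gm, cfg)
    ase <- simulateAseCounts(gm, cfg)
    cc <- .condCorAtCausal(st, gm)
    es <- effectSizeTest(cc$rSe, cc$rNse, cc$nSe, cc$nNse)
    da <- differentialAseTest(
        computeAse(ase),
        unique(ase[, c("individual", "gene", "eqtlGenotype")]))
    m <- merge(data.frame(gene = cc$gene, pEffectSize = es$p),
               da[da$testable & !is.na(da$pDiff),
                  c("gene", "pDiff")], by = "gene")
    names(m)[names(m) == "pDiff"] <- "pDiffAse"
    m
}

#' Recovery and FDR of the combined discovery procedure
#'
#' Repeatedly simulates a study containing \code{nSignal} genes with an
#' SE-specific cis effect among \code{nNull} genes with none, runs the
#' full effect-size + differential-ASE discovery arm (pooled best-SNP
#' selection, effect-size test, ASE aggregation, concordance, combined
#' BH), and records per replicate the sensitivity on the signal genes
#' and the false-discovery proportion.
#'
#' @param nReplicates replicate studies.
#' @param nSignal,nNull genes with and without an exposure-specific
#'   effect.
#' @param betaSe SE-condition effect of signal genes.
#' @param nIndividuals paired donors.
#' @param aseDepthMean allele-specific depth.
#' @param alphaNominal,fdr thresholds of the combined procedure.
#' @param seed integer seed; replicate r derives its generator seeds
#'   from it.
#' @return data.frame with columns \code{replicate},
#'   \code{sensitivity}, \code{fdp}, \code{nDiscoveries}.
#' @export
combinedRecoveryExperiment <- function(nReplicates = 50L, nSignal = 20L,
                                       nNull = 180L, betaSe = 0.8,
                                       nIndividuals = 150L,
                                       aseDepthMean = 50,
                                       alphaNominal = 0.05, fdr = 0.05,
                                       seed = 1L) {
    runArm <- function(nGenes, bSe, bNse, armSeed, tag) {
        cfg <- SimulationConfig(
            nIndividuals = as.integer(nIndividuals),
            nGenes = as.integer(nGenes), nSnpsPerGene = 5L,
            betaSe = bSe, betaNse = bNse,
            aseDepthMean = aseDepthMean, seed = armSeed)
        sim <- simulateStudy(cfg)
        res <- residualizeExpression(sim$study)
        hits <- suppressWarnings(
            selectBestEqtl(res, sim$genotypes, gate = 1))
        es <- cbind(hits, effectSizeTest(hits$rSe, hits$rNse,
                                         hits$nSe, hits$nNse))
        da <- differentialAseTest(
            computeAse(sim$ase), eqtlGenotypeClasses(sim$genotypes, es))
        es$gene <- paste0(tag, es$gene)
        da$gene <- paste0(tag, da$gene)
        list(es = es, da = da)
    }
    out <- lapply(seq_len(nReplicates), function(r) {
        sSig <- stageSeed(seed, "pipeline") + 2L * r
        sig <- runArm(nSignal, betaSe, 0, sSig, "sig_")
        nul <- runArm(nNull, 0, 0, sSig + 1L, "nul_")
        disc <- combinedDiscovery(rbind(sig$es, nul$es),
                                  rbind(sig$da, nul$da),
                                  alphaNominal = alphaNominal,
                                  fdr = fdr)
        hit <- disc$gene[disc$significant]
        data.frame(replicate = r,
                   sensitivity = mean(sig$es$gene %in% hit),
                   fdp = if (length(hit)) mean(startsWith(hit, "nul_"))
                         else 0,
                   nDiscoveries = length(hit))
    })
    do.call(rbind, out)
}
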