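test_that("config validation names the offending field", {
    expect_error(SimulationConfig(nIndividuals = 0), "nIndividuals")
    expect_error(SimulationConfig(mafRange = c(0.1, 0.6)), "mafRange")
    expect_error(SimulationConfig(pairedFraction = 0), "pairedFraction")
    expect_error(SimulationConfig(aseOverdispersion = 1),
                 "aseOverdispersion")
})

test_that("all generators are deterministic given the seed", {
    cfg <- SimulationConfig(nIndividuals = 15, nGenes = 3,
                            nSnpsPerGene = 2, seed = 11)
    a <- simulateStudy(cfg)
    b <- simulateStudy(cfg)
    expect_identical(dosages(a$genotypes), dosages(b$genotypes))
    expect_identical(exprMatrix(a$study), exprMatrix(b$study))
    expect_identical(a$ase, b$ase)
    p1 <- simulatePopulationFrequencies(10, 1, 0.2, 20, seed = 4)
    p2 <- simulatePopulationFrequencies(10, 1, 0.2, 20, seed = 4)
    expect_identical(panelPopulations(p1), panelPopulations(p2))
    expect_identical(panelBackground(p1), panelBackground(p2))
})

test_that("genotypes follow the configured allele frequency and phase", {
    cfg <- SimulationConfig(nIndividuals = 10000, nGenes = 1,
                            nSnpsPerGene = 2, mafRange = c(0.5, 0.5),
                            seed = 2)
    gm <- simulateGenotypes(cfg)
    emp <- colMeans(dosages(gm)) / 2
    expect_true(all(emp >= 0.48 & emp <= 0.52))
    # haplotype sum always equals dosage, including at n = 1
    cfg1 <- SimulationConfig(nIndividuals = 1, nGenes = 2,
                             nSnpsPerGene = 3, seed = 5)
    gm1 <- simulateGenotypes(cfg1)
    h <- haplotypes(gm1)
    expect_equal(nrow(dosages(gm1)), 1L)
    expect_identical(h$hap1 + h$hap2, dosages(gm1))
    # SNPs stay within the 1 Mb cis window of their gene's TSS
    off <- abs(GenomicRanges::start(snpRanges(gm)) -
               GenomicRanges::start(geneRanges(gm))[1])
    expect_true(all(off <= 1e6))
})

test_that("expression carries the condition-specific cis effect", {
    cfg <- SimulationConfig(nIndividuals = 500, nGenes = 4,
                            nSnpsPerGene = 1, betaSe = 1, betaNse = 0,
                            noiseSd = 0.1, individualSd = 0, seed = 3)
    gm <- simulateGenotypes(cfg)
    st <- simulateExpression(gm, cfg)
    cc <- condCor(st, gm)
    expect_true(all(cc$rSe > cc$rNse))
    # no signal, no noise: constant within machine tolerance
    cfg0 <- SimulationConfig(nIndividuals = 20, nGenes = 2,
                             betaSe = 0, betaNse = 0, noiseSd = 1e-12,
                             individualSd = 0, seed = 3)
    st0 <- simulateExpression(simulateGenotypes(cfg0), cfg0)
    expect_lt(max(apply(exprMatrix(st0), 1, sd)), 1e-9)
    # full pairing: every individual appears in exactly 2 metadata rows
    expect_true(all(table(sampleInfo(st)$individual) == 2))
})

test_that("latent cis effect is recovered by regression at n = 1000", {
    cfg <- SimulationConfig(nIndividuals = 1000, nGenes = 3,
                            nSnpsPerGene = 1, betaSe = 0.6,
                            betaNse = 0.2, seed = 9)
    gm <- simulateGenotypes(cfg)
    st <- simulateExpression(gm, cfg)
    info <- sampleInfo(st)
    dos <- dosages(gm)
    rownames(dos) <- individuals(gm)
    cs <- causalSnps(gm)
    for (g in rownames(exprMatrix(st))) {
        se <- info$condition == "SE"
        fit <- lm(log(exprMatrix(st)[g, se]) ~
                      dos[info$individual[se], cs[[g]]])
        est <- summary(fit)$coefficients[2, 1:2]
        expect_lt(abs(est[1] - 0.6) / est[2], 3)
    }
})

test_that("allele-specific counts have the logistic mean", {
    # beta = 0: heterozygote ratio centered at 1/2
    cfg0 <- SimulationConfig(nIndividuals = 300, nGenes = 40,
                             mafRange = c(0.5, 0.5), betaSe = 0,
                             betaNse = 0, aseDepthMean = 40,
                             aseOverdispersion = 0, seed = 21)
    ase0 <- simulateAseCounts(simulateGenotypes(cfg0), cfg0)
    het0 <- ase0[ase0$eqtlGenotype == "het", ]
    expect_gt(nrow(het0), 1e4)
    r0 <- het0$countAllele1 / (het0$countAllele1 + het0$countAllele2)
    expect_lt(abs(mean(r0, na.rm = TRUE) - 0.5), 0.01)
    # beta = 1: mean ratio near e/(1+e)
    cfg1 <- SimulationConfig(nIndividuals = 300, nGenes = 40,
                             mafRange = c(0.5, 0.5), betaSe = 1,
                             betaNse = 1, aseDepthMean = 40,
                             aseOverdispersion = 0, seed = 22)
    ase1 <- simulateAseCounts(simulateGenotypes(cfg1), cfg1)
    het1 <- ase1[ase1$eqtlGenotype == "het", ]
    r1 <- het1$countAllele1 / (het1$countAllele1 + het1$countAllele2)
    expect_lt(abs(mean(r1, na.rm = TRUE) - exp(1) / (1 + exp(1))), 0.01)
    # zero depth: nothing survives the read filter downstream
    cfgz <- SimulationConfig(nIndividuals = 5, nGenes = 2,
                             aseDepthMean = 0, seed = 1)
    asez <- simulateAseCounts(simulateGenotypes(cfgz), cfgz)
    expect_true(all(asez$countAllele1 + asez$countAllele2 == 0))
    expect_equal(nrow(computeAse(asez)), 0L)
})

test_that("population panel follows the environmental cline", {
    expect_error(simulatePopulationFrequencies(2, 1, 0.1, 5, seed = 1),
                 "nPops")
    # no slope, no drift: one shared frequency; cline statistic undefined
    p0 <- simulatePopulationFrequencies(10, 0, 0, 5, seed = 3)
    expect_equal(length(unique(panelPopulations(p0)$freq)), 1L)
    sr <- seasonalRadiation(panelClimate(p0),
                            panelPopulations(p0)$latitude)
    expect_true(is.na(clineStatistic(sr[, "winter"],
                                     panelPopulations(p0)$freq)))
    # strong slope, small drift: near-perfect rank correlation
    p1 <- simulatePopulationFrequencies(25, 8, 0.05, 5, seed = 3)
    sr1 <- seasonalRadiation(panelClimate(p1),
                             panelPopulations(p1)$latitude)
    expect_gt(clineStatistic(sr1[, "winter"],
                             panelPopulations(p1)$freq), 0.9)
    # background count contract
    p2 <- simulatePopulationFrequencies(10, 1, 0.2, 100, seed = 3)
    expect_equal(nrow(panelBackground(p2)), 100L)
})
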