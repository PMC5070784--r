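test_that("intercept-only residualization mean-centers each gene", {
    cfg <- SimulationConfig(nIndividuals = 15, nGenes = 3, seed = 2)
    st <- simulateExpression(simulateGenotypes(cfg), cfg)
    res <- residualizeExpression(st)
    expect_lt(max(abs(rowMeans(exprMatrix(res)))), 1e-10)
    # log of the raw assay is what gets centered
    expect_equal(exprMatrix(res),
                 log(exprMatrix(st)) - rowMeans(log(exprMatrix(st))))
})

test_that("residuals are orthogonal to covariates; perfect covariate
           zeroes its gene", {
    cfg <- SimulationConfig(nIndividuals = 40, nGenes = 5, seed = 7)
    st <- simulateExpression(simulateGenotypes(cfg), cfg)
    set.seed(1)
    covs <- cbind(a = rnorm(ncol(exprMatrix(st))),
                  b = rnorm(ncol(exprMatrix(st))))
    res <- residualizeExpression(st, covs)
    r <- exprMatrix(res)
    for (j in 1:2) {
        ip <- abs(r %*% covs[, j])
        bound <- 1e-8 * sqrt(rowSums(r^2)) * sqrt(sum(covs[, j]^2))
        expect_true(all(ip <= pmax(bound, 1e-12)))
    }
    g1 <- log(exprMatrix(st))[1, ]
    res2 <- residualizeExpression(st, cbind(g1 = g1))
    expect_lt(max(abs(exprMatrix(res2)[1, ])), 1e-8)
    # rank deficiency is reported with the offending column
    expect_error(
        residualizeExpression(st, cbind(x = covs[, 1], y = covs[, 1])),
        "rank-deficient")
})

test_that("fisherZ matches its closed form and clamps at the boundary", {
    expect_identical(fisherZ(0), 0)
    expect_equal(fisherZ(0.5), 0.5 * log(3))
    r <- c(0.123, 0.8, 0.99)
    expect_equal(fisherZ(-r), -fisherZ(r))
    expect_warning(z1 <- fisherZ(1), "clamped")
    expect_true(is.finite(z1) && z1 > 13)
})

test_that("effect-size test statistic behaves as specified", {
    # identical correlations: t = 0, p = 1, for any n
    r <- effectSizeTest(0.4, 0.4, 120, 80)
    expect_identical(r$t, 0)
    expect_identical(r$p, 1)
    # label swap negates t, leaves p unchanged
    a <- effectSizeTest(0.6, 0.2, 100, 50)
    b <- effectSizeTest(0.2, 0.6, 50, 100)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    expect_identical(a$strongerGroup, "SE")
    expect_identical(b$strongerGroup, "NSE")
    # the printed formula, evaluated directly
    byHand <- (atanh(0.6) - atanh(0.2)) / sqrt(1 / 97 + 1 / 47)
    expect_equal(a$t, byHand)
    expect_equal(a$p, 2 * pnorm(-abs(byHand)))
    # undefined variance below n = 4
    expect_error(effectSizeTest(0.5, 0.1, 3, 50), "n <= 3")
})

test_that("selectBestEqtl picks the strongest SNP with the stated tie
           rule", {
    # single SNP, perfect monotone relation
    h1 <- matrix(c(0, 0, 1, 1, 0, 1), ncol = 1)
    h2 <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
    gm <- makeGenotypes(h1, h2, pos = 1.5e6)
    d <- as.vector(h1 + h2)
    ind <- rep(sprintf("i%d", 1:6), 2)
    expr <- matrix(exp(3 + 0.5 * d[rep(1:6, 2)]), nrow = 1,
                   dimnames = list("g1", NULL))
    st <- makeStudy(expr, individual = ind,
                    condition = rep(c("SE", "NSE"), each = 6))
    hit <- suppressWarnings(selectBestEqtl(st, gm, gate = 1))
    expect_equal(hit$snp, "s1")
    expect_equal(abs(hit$rho), 1)
    # two identical SNP columns: lower position wins
    gm2 <- makeGenotypes(cbind(h1, h1), cbind(h2, h2),
                         pos = c(1.8e6, 1.2e6))
    hit2 <- suppressWarnings(selectBestEqtl(st, gm2, gate = 1))
    expect_equal(hit2$snp, "s2")  # s2 sits at the lower position
    expect_equal(hit2$pos, 1.2e6)
})

test_that("selection is invariant to sample and SNP order", {
    cfg <- SimulationConfig(nIndividuals = 50, nGenes = 5,
                            nSnpsPerGene = 4, seed = 13)
    gm <- simulateGenotypes(cfg)
    st <- residualizeExpression(simulateExpression(gm, cfg))
    base <- selectBestEqtl(st, gm, gate = 1)
    set.seed(1)
    perm <- sample(ncol(exprMatrix(st)))
    stP <- ExpressionStudy(exprMatrix(st)[, perm],
                           SummarizedExperiment::rowRanges(st),
                           as.data.frame(sampleInfo(st))[perm, ],
                           valueScale = "residual")
    expect_equal(selectBestEqtl(stP, gm, gate = 1)[, c("gene", "snp")],
                 base[, c("gene", "snp")])
    sperm <- sample(length(snpRanges(gm)))
    h <- haplotypes(gm)
    gmP <- GenotypeMatrix(individuals(gm), snpRanges(gm)[sperm],
                          geneRanges(gm), h$hap1[, sperm],
                          h$hap2[, sperm])
    expect_equal(selectBestEqtl(st, gmP, gate = 1)[, c("gene", "snp")],
                 base[, c("gene", "snp")])
})

test_that("simulated causal SNPs are recovered from pooled selection", {
    cfg <- SimulationConfig(nIndividuals = 300, nGenes = 60,
                            nSnpsPerGene = 5, betaSe = 1, betaNse = 1,
                            noiseSd = 0.5, individualSd = 0, seed = 31)
    gm <- simulateGenotypes(cfg)
    st <- residualizeExpression(simulateExpression(gm, cfg))
    hits <- selectBestEqtl(st, gm, gate = 1)
    hitRate <- mean(hits$snp == causalSnps(gm)[hits$gene])
    expect_gte(hitRate, 0.95)
})
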