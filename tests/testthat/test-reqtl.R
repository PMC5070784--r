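test_that("quantile normalization matches the hand-computed reference", {
    m <- cbind(s1 = c(2, 1, 5), s2 = c(4, 3, 8))
    # sorted means: (1+3)/2 = 2, (2+4)/2 = 3, (5+8)/2 = 6.5
    expect_equal(unname(quantileNormalize(m)),
                 cbind(c(3, 2, 6.5), c(3, 2, 6.5)))
    # samples that are permutations of each other share one multiset
    m2 <- cbind(c(1, 9, 4, 7), c(7, 4, 9, 1))
    q2 <- quantileNormalize(m2)
    expect_equal(sort(q2[, 1]), sort(q2[, 2]))
    expect_equal(sort(q2[, 1]), c(1, 4, 7, 9))
    # identical samples are unchanged
    m3 <- cbind(c(1, 2, 3), c(1, 2, 3))
    expect_equal(unname(quantileNormalize(m3)), m3)
    # brute-force oracle on a random 3 x 4 matrix
    set.seed(6)
    m4 <- matrix(rexp(12), 3, 4)
    ref <- m4
    target <- rowMeans(apply(m4, 2, sort))
    for (j in 1:4) ref[, j] <- target[rank(m4[, j])]
    expect_equal(unname(quantileNormalize(m4)), ref)
    expect_warning(quantileNormalize(cbind(1:3)), "single sample")
})

test_that("fold-change pipeline applies zero substitution and rankit as
           specified", {
    # every sample holds the multiset {0, 0.7, 2} so quantile
    # normalization is the identity and the substitution can be traced
    expr <- matrix(c(0.7, 2.0, 0.0,
                     2.0, 0.0, 0.7,
                     0.0, 0.7, 2.0,
                     0.0, 0.7, 2.0,
                     0.7, 2.0, 0.0,
                     2.0, 0.0, 0.7),
                   nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
    st <- makeStudy(expr,
                    individual = c("i1", "i2", "i3", "i1", "i2", "i3"),
                    condition = c("SE", "SE", "SE", "NSE", "NSE", "NSE"))
    fc <- computeFoldChange(st)
    # g1: i1 = 0.7/0.7 (NSE zero substituted), i2 = 2/0.7,
    #     i3 = 0 -> 0.7 over 2
    lfc <- c(log(1), log(2 / 0.7), log(0.35))
    grid <- qnorm((rank(lfc) - 0.5) / 3)
    expect_equal(unname(fcValues(fc)[, "g1"]), grid)
    expect_equal(unname(fcZeroFlags(fc)[, "g1"]),
                 c(TRUE, FALSE, TRUE))
    # a rankit column at n = 5 is the stated quantile grid
    set.seed(2)
    expr5 <- matrix(exp(rnorm(20)), nrow = 2,
                    dimnames = list(c("a", "b"), NULL))
    st5 <- makeStudy(expr5,
                     individual = rep(sprintf("i%d", 1:5), 2),
                     condition = rep(c("SE", "NSE"), each = 5))
    fc5 <- computeFoldChange(st5)
    expect_equal(unname(sort(fcValues(fc5)[, 1])),
                 qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)))
    # gene with SE = NSE for every individual: constant log fold
    # change, rank transform undefined, column dropped with a warning
    exprC <- matrix(c(1, 2, 4,  1, 4, 2,  2, 4, 1,  2, 1, 4),
                    nrow = 3,
                    dimnames = list(c("g1", "g2", "g3"), NULL))
    stC <- makeStudy(exprC,
                     individual = c("i1", "i1", "i2", "i2"),
                     condition = c("SE", "NSE", "SE", "NSE"))
    expect_warning(fcC <- computeFoldChange(stC), "constant")
    expect_false("g1" %in% colnames(fcValues(fcC)))
})

test_that("hidden-factor residualization removes an injected batch
           effect", {
    cfg <- SimulationConfig(nIndividuals = 60, nGenes = 30, seed = 23)
    sim <- simulateStudy(cfg)
    fc <- computeFoldChange(sim$study)
    expect_identical(hiddenFactorResidualize(fc, k = 0), fc)
    V <- fcValues(fc)
    batch <- rep(c(0, 1), length.out = nrow(V))
    Vb <- V + 3 * batch
    fcB <- new("FoldChangeMatrix",
               values = apply(Vb, 2, function(x)
                   qnorm((rank(x, ties.method = "first") - 0.5) /
                         length(x))),
               zeroFlag = fcZeroFlags(fc), genes = geneRanges(fc))
    fcR <- hiddenFactorResidualize(fcB, k = 1)
    r2 <- apply(fcValues(fcR), 2,
                function(y) summary(lm(y ~ batch))$r.squared)
    expect_lt(max(r2), 0.01)
    expect_error(hiddenFactorResidualize(fc, k = nrow(V)), "smaller")
    expect_warning(hiddenFactorResidualize(fc, k = nrow(V) - 1),
                   "overcorrection")
})

test_that("reQTL mapping recovers exact linear structure and skips
           constant SNPs", {
    set.seed(5)
    n <- 12
    h1 <- cbind(rbinom(n, 1, 0.5), 0, rbinom(n, 1, 0.5))
    h2 <- cbind(rbinom(n, 1, 0.5), 0, rbinom(n, 1, 0.5))
    gm <- makeGenotypes(h1, h2, pos = c(1.4e6, 1.6e6, 1.9e6))
    d <- (h1 + h2)[, 1]
    y <- qnorm((rank(d + seq_len(n) * 1e-6,
                     ties.method = "first") - 0.5) / n)
    V <- matrix(y, ncol = 1,
                dimnames = list(sprintf("i%d", 1:n), "g1"))
    fc <- new("FoldChangeMatrix", values = V,
              zeroFlag = matrix(FALSE, n, 1,
                                dimnames = dimnames(V)),
              genes = geneRanges(gm))
    res <- mapReqtl(fc, gm, mafMin = 0)
    expect_false("s2" %in% res$snp)    # constant dosage skipped
    expect_equal(res$snp[res$best], "s1")
    # best SNP carries (near) rank-perfect association
    expect_lt(res$p[res$best], res$p[!res$best][1])
})

test_that("empirical permutation p follows the add-one rule and its
           floor", {
    cfg <- SimulationConfig(nIndividuals = 40, nGenes = 4, betaSe = 3,
                            betaNse = 3, noiseSd = 0.05,
                            individualSd = 0, seed = 29)
    sim <- simulateStudy(cfg)
    # strong shared effect gives no fold-change signal: p not at floor
    fc <- computeFoldChange(sim$study)
    res <- permutationPvalue(fc, sim$genotypes, nPerm = 49, seed = 2)
    expect_true(all(res$pEmpirical >= 1 / 50))
    expect_true(all(res$pEmpirical <= 1))
    # noise-free construction: observed beats every permutation
    n <- 20
    set.seed(7)
    h <- cbind(rbinom(n, 1, 0.5))
    gm <- makeGenotypes(h, h, pos = 1.5e6)
    y <- qnorm((rank(2 * h[, 1] + rnorm(n, 0, 1e-4),
                     ties.method = "first") - 0.5) / n)
    V <- matrix(y, ncol = 1,
                dimnames = list(sprintf("i%d", 1:n), "g1"))
    fc1 <- new("FoldChangeMatrix", values = V,
               zeroFlag = matrix(FALSE, n, 1, dimnames = dimnames(V)),
               genes = geneRanges(gm))
    r1 <- permutationPvalue(fc1, gm, nPerm = 99, seed = 3, mafMin = 0)
    expect_equal(r1$pEmpirical, 1 / 100)
})

test_that("consistent individual shuffling leaves reQTL results
           unchanged", {
    cfg <- SimulationConfig(nIndividuals = 30, nGenes = 6, seed = 37)
    sim <- simulateStudy(cfg)
    fc <- computeFoldChange(sim$study)
    base <- permutationPvalue(fc, sim$genotypes, nPerm = 50, seed = 5)
    set.seed(1)
    perm <- sample(nrow(fcValues(fc)))
    fcP <- new("FoldChangeMatrix",
               values = fcValues(fc)[perm, , drop = FALSE],
               zeroFlag = fcZeroFlags(fc)[perm, , drop = FALSE],
               genes = geneRanges(fc))
    h <- haplotypes(sim$genotypes)
    iperm <- sample(length(individuals(sim$genotypes)))
    gmP <- GenotypeMatrix(individuals(sim$genotypes)[iperm],
                          snpRanges(sim$genotypes),
                          geneRanges(sim$genotypes),
                          h$hap1[iperm, ], h$hap2[iperm, ])
    again <- permutationPvalue(fcP, gmP, nPerm = 50, seed = 5)
    expect_equal(again, base)
})
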