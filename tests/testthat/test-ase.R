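aseRow <- function(ind, gene, cond, a1, a2, site = "x") {
    data.frame(individual = ind, gene = gene, condition = cond,
               site = site, countAllele1 = a1, countAllele2 = a2)
}

test_that("computeAse applies the read-depth and mono-allelic filters", {
    # (2,1): exactly at the 3-read boundary, retained
    out <- computeAse(aseRow("i1", "g1", "SE", 2, 1))
    expect_equal(out$ase, 2 / 3)
    expect_equal(out$totalReads, 3L)
    # (2,0): below the boundary, dropped
    expect_equal(nrow(computeAse(aseRow("i1", "g1", "SE", 2, 0))), 0L)
    # (30,0) site is mono-allelic; gene ASE uses the remaining site only
    two <- rbind(aseRow("i1", "g1", "SE", 30, 0, site = "a"),
                 aseRow("i1", "g1", "SE", 4, 6, site = "b"))
    out2 <- computeAse(two)
    expect_equal(out2$ase, 0.4)      # 4 / (4 + 6), by hand
    expect_equal(out2$totalReads, 10L)
    # (10,0) with < 15 total reads is extreme but not filtered
    out3 <- computeAse(aseRow("i1", "g1", "SE", 10, 0))
    expect_equal(out3$ase, 1)
    expect_error(computeAse(aseRow("i1", "g1", "SE", -1, 5)), "negative")
})

test_that("computeAse is invariant to row order and equivariant under
           allele swap", {
    set.seed(8)
    tab <- data.frame(individual = sample(sprintf("i%d", 1:6), 30,
                                          replace = TRUE),
                      gene = sample(c("g1", "g2"), 30, replace = TRUE),
                      condition = sample(c("SE", "NSE"), 30,
                                         replace = TRUE),
                      site = sample(c("a", "b"), 30, replace = TRUE),
                      countAllele1 = rpois(30, 5),
                      countAllele2 = rpois(30, 5))
    a <- computeAse(tab)
    b <- computeAse(tab[sample(30), ])
    expect_equal(a, b)
    swapped <- transform(tab, countAllele1 = countAllele2,
                         countAllele2 = countAllele1)
    expect_equal(computeAse(swapped)$ase, 1 - a$ase)
})

test_that("differential ASE separates shifted heterozygote groups and
           enforces the group-size rule", {
    set.seed(3)
    mk <- function(cond, cls, mu, n, from = 1) {
        data.frame(individual = sprintf("%s%s%d", cond, cls,
                                        seq(from, from + n - 1)),
                   gene = "g1", condition = cond,
                   ase = pmin(pmax(mu + rnorm(n, 0, 0.01), 0), 1),
                   totalReads = 20L)
    }
    obs <- rbind(mk("SE", "het", 0.5, 10), mk("NSE", "het", 0.8, 10),
                 mk("SE", "hom", 0.5, 10), mk("NSE", "hom", 0.5, 10))
    cls <- data.frame(individual = obs$individual, gene = "g1",
                      eqtlGenotype = rep(c("het", "hom"), each = 20))
    res <- differentialAseTest(obs, cls)
    expect_true(res$testable)
    expect_lt(res$pDiff, 1e-6)
    expect_identical(res$strongerGroup, "NSE")
    expect_identical(res$direction, 1)
    # 4 observations per group: below the >= 5 rule, untestable not error
    obs4 <- rbind(mk("SE", "het", 0.5, 4), mk("NSE", "het", 0.8, 4),
                  mk("SE", "hom", 0.5, 4), mk("NSE", "hom", 0.5, 4))
    cls4 <- data.frame(individual = obs4$individual, gene = "g1",
                       eqtlGenotype = rep(c("het", "hom"), each = 8))
    res4 <- differentialAseTest(obs4, cls4)
    expect_false(res4$testable)
    expect_true(is.na(res4$pDiff))
})

test_that("allele swap plus phase flip leaves the differential p
           unchanged and flips direction", {
    cfg <- SimulationConfig(nIndividuals = 60, nGenes = 2, betaSe = 1,
                            betaNse = 0, seed = 17)
    sim <- simulateStudy(cfg)
    obs <- computeAse(sim$ase)
    cls <- unique(sim$ase[, c("individual", "gene", "eqtlGenotype")])
    a <- differentialAseTest(obs, cls)
    swapped <- transform(sim$ase, countAllele1 = countAllele2,
                         countAllele2 = countAllele1)
    b <- differentialAseTest(computeAse(swapped), cls)
    expect_equal(a$pDiff, b$pDiff, tolerance = 1e-12)
    expect_equal(a$direction, -b$direction)
})

test_that("het vs hom QC separates classes under a strong cis effect", {
    cfg <- SimulationConfig(nIndividuals = 80, nGenes = 5,
                            mafRange = c(0.5, 0.5), betaSe = 1,
                            betaNse = 1, aseDepthMean = 50, seed = 19)
    sim <- simulateStudy(cfg)
    obs <- computeAse(sim$ase)
    cls <- unique(sim$ase[, c("individual", "gene", "eqtlGenotype")])
    qc <- aseQcHetVsHom(obs, cls)
    expect_lt(qc$p[qc$contrast == "het-vs-hom"], 1e-5)
    # the hom-vs-hom control carries no cis signal
    expect_gt(qc$p[qc$contrast == "hom:SE-vs-NSE"], 0.05)
    # identical lists for both classes: no separation
    obsEq <- obs
    clsEq <- rbind(
        data.frame(individual = obs$individual, gene = obs$gene,
                   eqtlGenotype = "het"),
        data.frame(individual = paste0(obs$individual, "x"),
                   gene = obs$gene, eqtlGenotype = "hom"))
    obsDup <- rbind(obs, transform(obs,
                                   individual = paste0(individual, "x")))
    qcEq <- aseQcHetVsHom(obsDup, unique(clsEq))
    expect_gt(qcEq$p[qcEq$contrast == "het-vs-hom"], 0.9)
})
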