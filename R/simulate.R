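#' @include AllClasses.R utils.R
NULL

# The sampling design (which individuals are observed in which condition)
# is shared by the expression and ASE generators. It is drawn from its own
# derived seed so the two generators agree without passing state.
.sampleDesign <- function(config) {
    set.seed(stageSeed(config@seed, "design"))
    n <- config@nIndividuals
    ind <- sprintf("ind%03d", seq_len(n))
    nPaired <- round(config@pairedFraction * n)
    paired <- sort(sample.int(n, nPaired))
    rows <- list()
    for (i in seq_len(n)) {
        conds <- if (i %in% paired) c("SE", "NSE")
                 else sample(c("SE", "NSE"), 1L)
        rows[[i]] <- data.frame(individual = ind[i], condition = conds,
                                stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    d$sample <- paste(d$individual, d$condition, sep = "-")
    d[, c("sample", "individual", "condition")]
}

#' Simulate phased genotypes under Hardy-Weinberg equilibrium
#'
#' Draws, for each gene, \code{nSnpsPerGene} biallelic SNPs within 1 Mb of
#' the gene's transcription start site, each with an ALT allele frequency
#' uniform in \code{mafRange}. Haplotypes are sampled independently per
#' chromosome copy (random mating), so dosages follow Hardy-Weinberg
#' proportions. Each gene lives on its own chromosome so cis windows never
#' overlap, and the middle SNP of each gene is designated causal.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GenotypeMatrix}; stored MAF is recomputed from
#'   the realized dosages.
#' @examples
#' gm <- simulateGenotypes(SimulationConfig(nIndividuals = 50, nGenes = 3))
#' gm
#' @export
simulateGenotypes <- function(config) {
    validObject(config)
    set.seed(stageSeed(config@seed, "genotypes"))
    n <- config@nIndividuals
    G <- config@nGenes
    S <- config@nSnpsPerGene
    tss <- 2e6
    ind <- sprintf("ind%03d", seq_len(n))
    geneIds <- sprintf("gene%04d", seq_len(G))
    genes <- GRanges(paste0("chr", seq_len(G)),
                     IRanges(start = tss, width = 1L))
    names(genes) <- geneIds

    freq <- runif(G * S, config@mafRange[1], config@mafRange[2])
    pos <- matrix(0L, G, S)
    for (g in seq_len(G))
        pos[g, ] <- sort(sample.int(2e6, S)) + as.integer(tss - 1e6)
    snpIds <- as.vector(t(outer(seq_len(G), seq_len(S),
                                function(g, j) sprintf("snp%04d_%d", g, j))))
    bases <- c("A", "C", "G", "T")
    refIdx <- sample.int(4, G * S, replace = TRUE)
    altIdx <- ((refIdx + sample.int(3, G * S, replace = TRUE)) - 1L) %% 4L + 1L
    causal <- rep(FALSE, S)
    causal[ceiling(S / 2)] <- TRUE

    snps <- GRanges(rep(paste0("chr", seq_len(G)), each = S),
                    IRanges(start = as.vector(t(pos)), width = 1L),
                    ref = bases[refIdx], alt = bases[altIdx],
                    gene = rep(geneIds, each = S),
                    causal = rep(causal, G))
    names(snps) <- snpIds

    hap1 <- matrix(rbinom(n * G * S, 1L, rep(freq, each = n)), nrow = n)
    hap2 <- matrix(rbinom(n * G * S, 1L, rep(freq, each = n)), nrow = n)
    GenotypeMatrix(individuals = ind, snps = snps, genes = genes,
                   hap1 = hap1, hap2 = hap2)
}

#' Simulate paired-condition expression with condition-specific cis effects
#'
#' For individual i in condition c, latent log expression of gene g is
#' \deqn{y = \mu_g + u_i + \beta_c d_{ig} + \varepsilon,} with
#' \eqn{u_i \sim N(0, \sigma_{ind}^2)} shared between the two conditions of
#' the same donor, \eqn{\varepsilon \sim N(0, \sigma^2)} independent per
#' sample, and \eqn{d_{ig}} the ALT-allele dosage at the gene's causal SNP.
#' Stored values are \code{exp(y)}, so the assay is nonnegative on an
#' RPKM-like scale and downstream stages re-log it.
#'
#' A \code{pairedFraction} subset of individuals receives both an SE and an
#' NSE sample; the remainder one condition at random.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} with causal SNPs
#'   designated (as produced by \code{\link{simulateGenotypes}}).
#' @param config the same \linkS4class{SimulationConfig}.
#' @return An \linkS4class{ExpressionStudy} (\code{valueScale = "raw"}).
#' @export
simulateExpression <- function(genotypes, config) {
    validObject(config)
    cs <- causalSnps(genotypes)
    if (length(cs) == 0)
        stop("genotypes carry no causal SNP designation")
    design <- .sampleDesign(config)
    set.seed(stageSeed(config@seed, "expression"))
    geneIds <- names(geneRanges(genotypes))
    cs <- cs[geneIds]
    dos <- dosages(genotypes)[, cs, drop = FALSE]  # individuals x genes
    dimnames(dos) <- list(individuals(genotypes), geneIds)

    mu <- 3
    u <- rnorm(length(individuals(genotypes)), 0, config@individualSd)
    names(u) <- individuals(genotypes)
    beta <- c(SE = config@betaSe, NSE = config@betaNse)

    nS <- nrow(design)
    G <- length(geneIds)
    lat <- matrix(mu, G, nS, dimnames = list(geneIds, design$sample))
    for (s in seq_len(nS)) {
        i <- design$individual[s]
        lat[, s] <- mu + u[i] + beta[[design$condition[s]]] * dos[i, ] +
            rnorm(G, 0, config@noiseSd)
    }
    ExpressionStudy(exp(lat), geneRanges(genotypes), design,
                    valueScale = "raw")
}

#' Simulate phased allele-specific read counts
#'
#' Emulates gene-level phased ASE data: every individual is assumed
#' heterozygous at an exonic site of each gene, and the counts are phased
#' onto the haplotype carrying the ALT allele of the gene's causal SNP
#' (allele1). Per (individual, gene, condition-sample) record, total depth
#' is Poisson(\code{aseDepthMean}) and \code{countAllele1} is
#' beta-binomial with mean \eqn{e^{\beta_c}/(1 + e^{\beta_c})} for eQTL
#' heterozygotes and 1/2 for eQTL homozygotes, with overdispersion
#' \code{aseOverdispersion}. With probability \code{phaseError} the two
#' counts of a record are swapped, emulating a phasing switch error.
#'
#' @inheritParams simulateExpression
#' @return data.frame with columns \code{individual}, \code{gene},
#'   \code{condition}, \code{site}, \code{countAllele1},
#'   \code{countAllele2}, \code{eqtlGenotype} (\code{"het"}/\code{"hom"};
#'   simulation truth, carried for convenience).
#' @export
simulateAseCounts <- function(genotypes, config) {
    validObject(config)
    cs <- causalSnps(genotypes)
    if (length(cs) == 0)
        stop("genotypes carry no causal SNP designation")
    design <- .sampleDesign(config)
    set.seed(stageSeed(config@seed, "ase"))
    geneIds <- names(geneRanges(genotypes))
    cs <- cs[geneIds]
    dos <- dosages(genotypes)[, cs, drop = FALSE]
    dimnames(dos) <- list(individuals(genotypes), geneIds)

    tab <- expand.grid(sampleRow = seq_len(nrow(design)),
                       gene = geneIds, stringsAsFactors = FALSE)
    tab$individual <- design$individual[tab$sampleRow]
    tab$condition <- design$condition[tab$sampleRow]
    het <- dos[cbind(tab$individual, tab$gene)] == 1
    beta <- ifelse(tab$condition == "SE", config@betaSe, config@betaNse)
    p <- ifelse(het, plogis(beta), 0.5)

    m <- nrow(tab)
    depth <- rpois(m, config@aseDepthMean)
    a1 <- rbetabinom(m, depth, p, config@aseOverdispersion)
    a2 <- depth - a1
    if (config@phaseError > 0) {
        flip <- runif(m) < config@phaseError
        tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
    }
    data.frame(individual = tab$individual, gene = tab$gene,
               condition = tab$condition,
               site = paste0(tab$gene, "_ex1"),
               countAllele1 = a1, countAllele2 = a2,
               eqtlGenotype = ifelse(het, "het", "hom"),
               stringsAsFactors = FALSE)
}

#' Simulate population allele frequencies on an environmental cline
#'
#' Populations are placed on a latitudinal gradient with monthly radiation
#' values that peak in July in the northern hemisphere and in January in
#' the southern. The focal SNP's frequency follows a logistic cline in the
#' standardized winter radiation plus Gaussian drift on the logit scale;
#' background SNPs drift around population-free logit means with no
#' environmental term. Regional groups are latitude bands.
#'
#' @param nPops number of populations (>= 3).
#' @param envSlope slope of the focal cline on the logit scale per
#'   standardized unit of winter radiation.
#' @param driftSd s.d. of logit-scale drift noise per population.
#' @param nBackground number of neutral background SNPs.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PopulationPanel}.
#' @export
simulatePopulationFrequencies <- function(nPops = 30L, envSlope = 2,
                                          driftSd = 0.3,
                                          nBackground = 1000L, seed = 1L) {
    if (nPops < 3) stop("nPops must be >= 3")
    set.seed(stageSeed(seed, "population"))
    lat <- sort(runif(nPops, -45, 65))
    lon <- runif(nPops, -180, 180)
    popIds <- sprintf("pop%03d", seq_len(nPops))

    # Monthly downward short-wave radiation, W m^-2: annual mean declines
    # with |latitude|; the seasonal cycle peaks mid-July (m = 7) north of
    # the equator and mid-January south of it.
    months <- 1:12
    climate <- t(vapply(seq_len(nPops), function(p) {
        260 - 1.2 * abs(lat[p]) +
            1.4 * lat[p] * cos(2 * pi * (months - 7) / 12)
    }, numeric(12)))
    dimnames(climate) <- list(popIds, sprintf("m%02d", months))

    sr <- seasonalRadiation(climate, lat)
    env <- sr[, "winter"]
    envZ <- if (sd(env) > 0) (env - mean(env)) / sd(env) else env * 0

    focal <- plogis(envSlope * envZ + rnorm(nPops, 0, driftSd))
    bg <- matrix(NA_real_, nBackground, nPops,
                 dimnames = list(sprintf("bg%04d", seq_len(nBackground)),
                                 popIds))
    if (nBackground > 0) {
        a <- rnorm(nBackground, 0, 1)
        bg[] <- plogis(a + rnorm(nBackground * nPops, 0, driftSd))
    }

    group <- cut(lat, breaks = c(-90, -10, 20, 45, 90),
                 labels = c("southern", "tropical", "temperate", "northern"))
    pops <- data.frame(population = popIds, group = as.character(group),
                       latitude = lat, longitude = lon,
                       n = sample(5:50, nPops, replace = TRUE),
                       freq = pmin(pmax(unname(focal), 0), 1),
                       stringsAsFactors = FALSE, row.names = NULL)
    new("PopulationPanel", populations = pops, background = bg,
        climate = climate)
}

#' Simulate a complete paired-condition study
#'
#' Convenience wrapper running \code{\link{simulateGenotypes}},
#' \code{\link{simulateExpression}} and \code{\link{simulateAseCounts}}
#' with one config.
#'
#' @inheritParams simulateGenotypes
#' @return list with elements \code{genotypes}, \code{study}, \code{ase}.
#' @export
simulateStudy <- function(config = SimulationConfig()) {
    gm <- simulateGenotypes(config)
    list(genotypes = gm,
         study = simulateExpression(gm, config),
         ase = simulateAseCounts(gm, config))
}
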