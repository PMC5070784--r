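#' @include AllClasses.R utils.R
NULL

#' Gene-level phased allele-specific expression
#'
#' Aggregates per-site phased allele counts to one ASE observation per
#' (individual, gene, condition):
#' \code{ase = countAllele1 / (countAllele1 + countAllele2)}, where
#' allele1 is the expressed haplotype in phase with the designated allele
#' of the gene's regulatory SNP. Two filters are applied:
#' \itemize{
#'   \item mono-allelic sites — sites with zero reads on one allele and at
#'     least \code{monoTotalMin} reads in total are excluded before
#'     summation, as such sites usually reflect mapping or genotyping
#'     artifacts rather than extreme regulation;
#'   \item minimum depth — aggregated observations with fewer than
#'     \code{minReads} total reads are dropped.
#' }
#'
#' @param counts data.frame with columns \code{individual}, \code{gene},
#'   \code{condition}, \code{countAllele1}, \code{countAllele2} and
#'   optionally \code{site} (one row per exonic site; without \code{site}
#'   each row is treated as a site record).
#' @param minReads minimum total reads per retained observation
#'   (default 3).
#' @param monoTotalMin total-read threshold above which a zero count on
#'   one allele marks a site mono-allelic (default 15).
#' @return data.frame with columns \code{individual}, \code{gene},
#'   \code{condition}, \code{ase}, \code{totalReads}; one row per retained
#'   observation, ordered by (gene, individual, condition).
#' @examples
#' computeAse(data.frame(individual = "i1", gene = "g1", condition = "SE",
#'                       countAllele1 = 2, countAllele2 = 1))
#' @export
computeAse <- function(counts, minReads = 3L, monoTotalMin = 15L) {
    need <- c("individual", "gene", "condition",
              "countAllele1", "countAllele2")
    if (!all(need %in% names(counts)))
        stop("counts must contain columns: ", paste(need, collapse = ", "))
    a1 <- counts$countAllele1
    a2 <- counts$countAllele2
    if (any(a1 < 0 | a2 < 0, na.rm = TRUE))
        stop("negative allele counts")
    tot <- a1 + a2
    mono <- (a1 == 0 | a2 == 0) & tot >= monoTotalMin
    keep <- counts[!mono, , drop = FALSE]
    if (nrow(keep) == 0)
        return(data.frame(individual = character(0), gene = character(0),
                          condition = character(0), ase = numeric(0),
                          totalReads = integer(0)))
    key <- paste(keep$gene, keep$individual, keep$condition, sep = "\r")
    s1 <- rowsum(keep$countAllele1, key)
    s2 <- rowsum(keep$countAllele2, key)
    parts <- do.call(rbind, strsplit(rownames(s1), "\r", fixed = TRUE))
    out <- data.frame(individual = parts[, 2], gene = parts[, 1],
                      condition = parts[, 3], ase = s1[, 1] / (s1 + s2)[, 1],
                      totalReads = as.integer((s1 + s2)[, 1]),
                      stringsAsFactors = FALSE)
    out <- out[out$totalReads >= minReads, , drop = FALSE]
    out <- out[order(out$gene, out$individual, out$condition), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genotype class of each individual at a gene's eQTL
#'
#' Helper mapping eQTL hits back onto the genotype matrix: individuals
#' heterozygous at the gene's selected SNP are labelled \code{"het"},
#' homozygotes \code{"hom"}; individuals with a missing genotype at the
#' eQTL are omitted.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param hits data.frame with columns \code{gene}, \code{snp} (e.g. from
#'   \code{\link{selectBestEqtl}}).
#' @return data.frame with columns \code{individual}, \code{gene},
#'   \code{eqtlGenotype}.
#' @export
eqtlGenotypeClasses <- function(genotypes, hits) {
    dos <- dosages(genotypes)
    rownames(dos) <- individuals(genotypes)
    out <- lapply(seq_len(nrow(hits)), function(i) {
        d <- dos[, hits$snp[i]]
        ok <- !is.na(d)
        data.frame(individual = rownames(dos)[ok], gene = hits$gene[i],
                   eqtlGenotype = ifelse(d[ok] == 1, "het", "hom"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

.aseGroupKey <- function(condition, class) paste(condition, class, sep = "-")

#' Differential allele-specific expression between exposure groups
#'
#' For each gene, compares phased ASE between the SE heterozygotes and NSE
#' heterozygotes at the gene's eQTL by Welch's two-sample t-test. ASE is
#' oriented so that values above 1/2 favor the designated eQTL allele;
#' only heterozygotes are informative because a cis effect produces
#' allelic imbalance only when the regulatory alleles differ between
#' haplotypes. A gene is testable only if each of the four groups (SE-hom,
#' SE-het, NSE-hom, NSE-het) has at least \code{minGroupObs} observations,
#' which protects against comparing conditions with unbalanced coverage.
#'
#' @param observations output of \code{\link{computeAse}}.
#' @param eqtlClasses data.frame with columns \code{individual},
#'   \code{gene}, \code{eqtlGenotype} in \{"het", "hom"\} (see
#'   \code{\link{eqtlGenotypeClasses}}).
#' @param minGroupObs minimum observations per group (default 5).
#' @return data.frame, one row per gene present in both inputs:
#'   group sizes \code{nSeHom}, \code{nSeHet}, \code{nNseHom},
#'   \code{nNseHet}; group means \code{meanSeHet}, \code{meanNseHet},
#'   \code{meanSeHom}, \code{meanNseHom}; \code{pDiff} (Welch t, two-sided;
#'   NA when untestable); \code{strongerGroup}, the heterozygote group with
#'   larger \eqn{|mean - 1/2|}; \code{direction}, +1 if the stronger
#'   group's imbalance favors the phased eQTL allele, -1 otherwise;
#'   \code{testable}.
#' @export
differentialAseTest <- function(observations, eqtlClasses,
                                minGroupObs = 5L) {
    obs <- merge(observations, eqtlClasses, by = c("individual", "gene"))
    byGene <- split(obs, obs$gene)
    out <- lapply(names(byGene), function(g) {
        o <- byGene[[g]]
        grp <- .aseGroupKey(o$condition, o$eqtlGenotype)
        n <- function(k) sum(grp == k)
        m <- function(k) if (n(k)) mean(o$ase[grp == k]) else NA_real_
        ns <- c(nSeHom = n("SE-hom"), nSeHet = n("SE-het"),
                nNseHom = n("NSE-hom"), nNseHet = n("NSE-het"))
        testable <- all(ns >= minGroupObs)
        p <- NA_real_; stronger <- NA_character_; dir <- NA_real_
        mSeHet <- m("SE-het"); mNseHet <- m("NSE-het")
        if (testable) {
            p <- tryCatch(
                stats::t.test(o$ase[grp == "SE-het"],
                              o$ase[grp == "NSE-het"])$p.value,
                error = function(e) NA_real_)
            stronger <- if (abs(mSeHet - 0.5) >= abs(mNseHet - 0.5))
                "SE" else "NSE"
            mStronger <- if (stronger == "SE") mSeHet else mNseHet
            dir <- sign(mStronger - 0.5)
        }
        data.frame(gene = g, nSeHom = ns[["nSeHom"]],
                   nSeHet = ns[["nSeHet"]], nNseHom = ns[["nNseHom"]],
                   nNseHet = ns[["nNseHet"]],
                   meanSeHet = mSeHet, meanNseHet = mNseHet,
                   meanSeHom = m("SE-hom"), meanNseHom = m("NSE-hom"),
                   pDiff = p, strongerGroup = stronger, direction = dir,
                   testable = testable, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene = character(0), nSeHom = integer(0),
                          nSeHet = integer(0), nNseHom = integer(0),
                          nNseHet = integer(0), meanSeHet = numeric(0),
                          meanNseHet = numeric(0), meanSeHom = numeric(0),
                          meanNseHom = numeric(0), pDiff = numeric(0),
                          strongerGroup = character(0),
                          direction = numeric(0), testable = logical(0))
    rownames(res) <- NULL
    res
}

#' ASE magnitude QC: eQTL heterozygotes vs homozygotes
#'
#' If the selected eQTLs are genuine cis-regulatory variants, allelic
#' imbalance \eqn{|ASE - 1/2|} should be larger in individuals
#' heterozygous at the eQTL than in homozygotes. This report runs
#' two-sided Wilcoxon rank-sum tests of that contrast overall and within
#' each exposure condition, plus a hom-vs-hom contrast between conditions
#' as a no-bias control (expected non-significant: homozygotes carry no
#' cis signal in either condition).
#'
#' @inheritParams differentialAseTest
#' @return data.frame with one row per contrast: \code{contrast},
#'   \code{nA}, \code{nB}, \code{medianA}, \code{medianB}, \code{p}.
#'   Contrasts with an empty class are omitted with a warning.
#' @export
aseQcHetVsHom <- function(observations, eqtlClasses) {
    obs <- merge(observations, eqtlClasses, by = c("individual", "gene"))
    obs$dev <- abs(obs$ase - 0.5)
    pick <- function(cond, cls) {
        sel <- obs$eqtlGenotype == cls
        if (!is.null(cond)) sel <- sel & obs$condition == cond
        obs$dev[sel]
    }
    contrasts <- list(
        `het-vs-hom` = list(pick(NULL, "het"), pick(NULL, "hom")),
        `SE:het-vs-hom` = list(pick("SE", "het"), pick("SE", "hom")),
        `NSE:het-vs-hom` = list(pick("NSE", "het"), pick("NSE", "hom")),
        `hom:SE-vs-NSE` = list(pick("SE", "hom"), pick("NSE", "hom")))
    rows <- lapply(names(contrasts), function(nm) {
        a <- contrasts[[nm]][[1]]; b <- contrasts[[nm]][[2]]
        if (length(a) < 2 || length(b) < 2) {
            warning("contrast ", nm, " omitted: empty or near-empty class")
            return(NULL)
        }
        p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
        data.frame(contrast = nm, nA = length(a), nB = length(b),
                   medianA = stats::median(a), medianB = stats::median(b),
                   p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(res) <- NULL
    res
}
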