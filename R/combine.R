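#' @include AllClasses.R
NULL

#' Directional concordance between the effect-size and differential-ASE
#' tests
#'
#' Two conditions must hold for a gene to count as concordant:
#' \enumerate{
#'   \item the same sample group (SE or NSE) exhibits the stronger effect
#'     in both tests — \eqn{|z|} for the effect-size test,
#'     \eqn{|\bar{ase} - 1/2|} of the heterozygote group for the ASE test;
#'   \item the same allele is the upregulating allele: the sign of the
#'     eQTL correlation in the stronger condition (positive = ALT-counted
#'     allele increases expression) must match the direction of the
#'     allelic imbalance (positive = favors the phased eQTL allele).
#' }
#' Genes whose ASE test is untestable are non-concordant, with the reason
#' recorded.
#'
#' @param es data.frame with columns \code{strongerGroup}, \code{rSe},
#'   \code{rNse} (effect-size side, e.g. \code{\link{selectBestEqtl}}
#'   merged with \code{\link{effectSizeTest}}).
#' @param da data.frame with columns \code{strongerGroup},
#'   \code{direction}, \code{testable} (from
#'   \code{\link{differentialAseTest}}), row-aligned with \code{es}.
#' @return logical vector with attribute \code{"reason"} (character;
#'   \code{NA} for concordant genes).
#' @export
isConcordant <- function(es, da) {
    stopifnot(nrow(es) == nrow(da))
    rStronger <- ifelse(es$strongerGroup == "SE", es$rSe, es$rNse)
    sameGroup <- es$strongerGroup == da$strongerGroup
    sameAllele <- sign(rStronger) == sign(da$direction)
    ok <- !is.na(da$testable) & da$testable
    conc <- ok & !is.na(sameGroup) & sameGroup &
        !is.na(sameAllele) & sameAllele
    reason <- rep(NA_character_, nrow(es))
    reason[!ok] <- "ASE untestable"
    reason[ok & !sameGroup] <- "stronger group differs"
    reason[ok & sameGroup & !sameAllele] <- "upregulating allele differs"
    structure(conc, reason = reason)
}

#' Exact two-sided binomial test of concordance enrichment
#'
#' Tests whether the observed number of directionally concordant genes
#' exceeds (or falls short of) the background concordance fraction, by the
#' exact two-sided binomial test: the p-value sums the probabilities of
#' all outcomes no more likely than the observed count (the "minlike"
#' convention). The background fraction should be computed from the full
#' set of genes with both tests defined, not fixed a priori.
#'
#' @param nConcordant observed concordant count.
#' @param nTotal number of genes tested.
#' @param backgroundFraction expected concordance probability in (0, 1).
#' @return two-sided exact p-value.
#' @examples
#' concordanceBinomialTest(10, 10, 0.5)  # 2 * 0.5^10
#' @export
concordanceBinomialTest <- function(nConcordant, nTotal,
                                    backgroundFraction) {
    if (nTotal == 0) stop("nTotal must be positive")
    if (nConcordant < 0 || nConcordant > nTotal)
        stop("nConcordant must lie in [0, nTotal]")
    if (backgroundFraction <= 0 || backgroundFraction >= 1)
        stop("backgroundFraction must lie in (0, 1)")
    d <- dbinom(0:nTotal, nTotal, backgroundFraction)
    pObs <- d[nConcordant + 1]
    # relative tolerance guards against floating-point ties (as in
    # stats::binom.test)
    min(1, sum(d[d <= pObs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity; input p-values must lie in (0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values, same length and order as the input.
#' @export
bhFdr <- function(pvalues) {
    if (length(pvalues) == 0) return(numeric(0))
    if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Combined two-test discovery of exposure-dependent eQTLs
#'
#' Implements the intersection procedure: the candidate set consists of
#' genes with a nominally significant effect-size test
#' (\code{p < alphaNominal}) AND directionally concordant differential
#' ASE; Benjamini-Hochberg FDR control is then applied to the
#' differential-ASE p-values WITHIN that candidate set, and a gene is
#' called significant when its q-value is below \code{fdr}. Because the
#' two tests draw on different contrasts of the same data (across- vs
#' within-individual), requiring both to agree sharply limits false
#' positives from either source alone. Note the q-values are conditional
#' on the nominal filter; they control FDR within the filtered set.
#'
#' @param es data.frame with one row per gene: \code{gene}, \code{snp},
#'   \code{rSe}, \code{rNse}, \code{zSe}, \code{zNse}, \code{t}, \code{p},
#'   \code{strongerGroup} (effect-size side).
#' @param da differential-ASE results (\code{\link{differentialAseTest}});
#'   matched to \code{es} by \code{gene}.
#' @param alphaNominal nominal effect-size threshold (default 0.05).
#' @param fdr FDR threshold on the combined q-values (default 0.05).
#' @return data.frame with one row per gene of \code{es}: both tests'
#'   fields (ASE columns prefixed \code{ase}), \code{concordant},
#'   \code{concordanceReason}, \code{candidate}, \code{combinedQ} (NA off
#'   the candidate set) and \code{significant}. An empty candidate set
#'   yields zero significant genes, not an error.
#' @export
combinedDiscovery <- function(es, da, alphaNominal = 0.05, fdr = 0.05) {
    daM <- da[match(es$gene, da$gene), , drop = FALSE]
    conc <- isConcordant(es, daM)
    res <- es
    res$aseStrongerGroup <- daM$strongerGroup
    res$aseDirection <- daM$direction
    res$asePDiff <- daM$pDiff
    res$aseTestable <- !is.na(daM$testable) & daM$testable
    res$concordant <- as.logical(conc)
    res$concordanceReason <- attr(conc, "reason")
    res$candidate <- !is.na(res$p) & res$p < alphaNominal & res$concordant &
        !is.na(res$asePDiff)
    res$combinedQ <- NA_real_
    if (any(res$candidate))
        res$combinedQ[res$candidate] <- bhFdr(res$asePDiff[res$candidate])
    res$significant <- res$candidate & !is.na(res$combinedQ) &
        res$combinedQ < fdr
    rownames(res) <- NULL
    res
}
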