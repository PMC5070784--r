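#' @include AllClasses.R utils.R
NULL

#' Regress covariates out of an expression matrix
#'
#' Per gene, replaces expression by the ordinary-least-squares residuals of
#' expression on the supplied covariates plus an intercept. Raw-scale
#' studies are log-transformed first (zeros replaced by half the gene's
#' minimum nonzero value), matching the convention that association stages
#' operate on normalized log expression.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param covariates numeric matrix with one row per sample (column order
#'   of the study), or NULL for intercept-only (mean centering).
#' @param log log-transform raw-scale values first (default TRUE; ignored
#'   for studies already on log or residual scale).
#' @return An \linkS4class{ExpressionStudy} with
#'   \code{valueScale = "residual"}; residuals are orthogonal to every
#'   covariate column.
#' @examples
#' sim <- simulateStudy(SimulationConfig(nIndividuals = 20, nGenes = 2))
#' res <- residualizeExpression(sim$study)
#' max(abs(rowMeans(exprMatrix(res))))  # mean-centered
#' @export
residualizeExpression <- function(study, covariates = NULL, log = TRUE) {
    m <- exprMatrix(study)
    scale <- metadata(study)$valueScale
    if (identical(scale, "raw") && log) {
        pos <- m
        pos[pos == 0] <- NA
        gmin <- apply(pos, 1, min, na.rm = TRUE) / 2
        m[m == 0] <- gmin[row(m)[m == 0]]
        m <- base::log(m)
    }
    X <- cbind(`(intercept)` = rep(1, ncol(m)))
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        if (nrow(covariates) != ncol(m))
            stop("covariates must have one row per sample")
        if (is.null(colnames(covariates)))
            colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
        X <- cbind(X, covariates)
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
            drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
            stop("rank-deficient covariates: ", paste(drop, collapse = ", "))
        }
    }
    fit <- lm.fit(X, t(m))
    resid <- t(as.matrix(fit$residuals))
    dimnames(resid) <- dimnames(m)
    ExpressionStudy(resid, rowRanges(study),
                    as.data.frame(colData(study)), valueScale = "residual")
}

#' Fisher z-transform of a correlation coefficient
#'
#' \eqn{z = \frac{1}{2}\log\frac{1+r}{1-r}}; the variance-stabilizing
#' transform under which a sample correlation is approximately
#' \eqn{N(z(\rho), 1/(n-3))}. Correlations at the boundary (finite-sample
#' perfect association) are clamped to \eqn{\pm(1 - 10^{-12})} with a
#' warning rather than returning infinity.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of z-scores; odd function of \code{r}.
#' @examples
#' fisherZ(0.5)  # 0.5 * log(3)
#' @export
fisherZ <- function(r) {
    if (any(abs(r) >= 1, na.rm = TRUE)) {
        warning("correlation at +/-1 clamped to +/-(1 - 1e-12)")
        r <- sign(r) * pmin(abs(r), 1 - 1e-12)
    }
    0.5 * base::log((1 + r) / (1 - r))
}

#' Between-condition effect-size test for an eQTL
#'
#' Tests whether a cis-eQTL's effect differs between the sun-exposed (SE)
#' and non-sun-exposed (NSE) sample groups by comparing Fisher
#' z-transformed Pearson correlations:
#' \deqn{t = \frac{z_{SE} - z_{NSE}}
#'   {\sqrt{1/(n_{SE}-3) + 1/(n_{NSE}-3)}},}
#' which is standard normal under the null of equal population
#' correlations. Comparing effect sizes rather than per-group significance
#' avoids false positives from unequal power: low power in one group only
#' reduces sensitivity, never creates spurious differences.
#'
#' @param rSe,rNse Pearson correlations between dosage and expression in
#'   the SE and NSE samples (vectorized).
#' @param nSe,nNse sample counts behind each correlation; both must
#'   be >= 4 so the z variance \eqn{1/(n-3)} is defined.
#' @return data.frame with columns \code{zSe}, \code{zNse}, \code{t},
#'   \code{p} (two-sided normal) and \code{strongerGroup}, the condition
#'   with the larger \eqn{|z|} (\code{"SE"} on exact ties).
#' @examples
#' effectSizeTest(rSe = 0.1, rNse = 0.6, nSe = 300, nNse = 200)
#' @export
effectSizeTest <- function(rSe, rNse, nSe, nNse) {
    if (any(nSe <= 3 | nNse <= 3, na.rm = TRUE))
        stop("effect-size test undefined for n <= 3 in either condition")
    zSe <- fisherZ(rSe)
    zNse <- fisherZ(rNse)
    t <- (zSe - zNse) / sqrt(1 / (nSe - 3) + 1 / (nNse - 3))
    p <- 2 * pnorm(abs(t), lower.tail = FALSE)
    data.frame(zSe = zSe, zNse = zNse, t = t, p = p,
               strongerGroup = ifelse(abs(zSe) >= abs(zNse), "SE", "NSE"),
               stringsAsFactors = FALSE)
}

#' Select the strongest local eQTL per gene from pooled samples
#'
#' For each gene, tests every SNP within \code{windowBp} of the TSS (MAF
#' above \code{mafMin}) by Spearman correlation between ALT dosage and
#' expression across ALL samples pooled over conditions, and keeps the SNP
#' with the largest \eqn{|\rho|}. Selecting on pooled data removes the
#' winner's-curse bias that arises when the strongest per-group eQTL is
#' re-tested in the other group. Ties are broken by smaller genomic
#' position, then lexicographic SNP id. A gene passes the significance
#' gate when its pooled p-value, Bonferroni-adjusted for the number of
#' SNPs tested in its window, is below \code{gate}.
#'
#' Per-condition Pearson correlations (the inputs of
#' \code{\link{effectSizeTest}}) are computed for the selected SNP on the
#' same expression values, pairwise-complete over missing genotypes.
#'
#' @param study an \linkS4class{ExpressionStudy}, typically residualized.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param windowBp cis-window half-width around the TSS (default 1e6).
#' @param mafMin minimum minor allele frequency, exclusive (default 0.05).
#' @param gate pooled-association significance gate (default 0.05); set to
#'   1 to keep every gene.
#' @return data.frame, one row per gene with >= 1 SNP in its window:
#'   \code{gene}, \code{snp}, \code{chrom}, \code{pos}, \code{rho}
#'   (pooled Spearman), \code{nPooled}, \code{pPooled},
#'   \code{nSnpsTested}, \code{gatePassed}, \code{rSe}, \code{nSe},
#'   \code{rNse}, \code{nNse}, \code{upregAlleleSe}, \code{upregAlleleNse}
#'   (the allele associated with higher expression in each condition).
#'   Genes with an empty window are dropped with a warning.
#' @export
selectBestEqtl <- function(study, genotypes, windowBp = 1e6,
                           mafMin = 0.05, gate = 0.05) {
    expr <- exprMatrix(study)
    info <- colData(study)
    dos <- dosages(genotypes)
    rownames(dos) <- individuals(genotypes)
    sampDos <- dos[info$individual, , drop = FALSE]
    snps <- snpRanges(genotypes)
    genes <- rowRanges(study)
    isSe <- info$condition == "SE"

    out <- vector("list", length(genes))
    skipped <- character(0)
    for (g in seq_along(genes)) {
        geneId <- names(genes)[g]
        tss <- start(genes)[g]
        inWin <- as.character(seqnames(snps)) ==
                     as.character(seqnames(genes))[g] &
                 abs(start(snps) - tss) <= windowBp &
                 mcols(snps)$maf > mafMin
        if (!any(inWin)) { skipped <- c(skipped, geneId); next }
        cand <- which(inWin)
        y <- expr[geneId, ]
        D <- sampDos[, cand, drop = FALSE]
        rho <- suppressWarnings(
            as.vector(cor(y, D, method = "spearman",
                          use = "pairwise.complete.obs")))
        rho[is.na(rho)] <- 0  # zero-variance dosage columns
        ord <- order(-abs(rho), start(snps)[cand], names(snps)[cand])
        best <- ord[1]
        j <- cand[best]
        dBest <- sampDos[, j]
        okAll <- !is.na(dBest) & !is.na(y)
        nPooled <- sum(okAll)
        pPooled <- corPvalue(rho[best], nPooled)
        rSe <- suppressWarnings(cor(y[isSe], dBest[isSe],
                                    use = "pairwise.complete.obs"))
        rNse <- suppressWarnings(cor(y[!isSe], dBest[!isSe],
                                     use = "pairwise.complete.obs"))
        nSe <- sum(okAll & isSe)
        nNse <- sum(okAll & !isSe)
        upreg <- function(r) {
            if (is.na(r) || r == 0) NA_character_
            else if (r > 0) mcols(snps)$alt[j] else mcols(snps)$ref[j]
        }
        out[[g]] <- data.frame(
            gene = geneId, snp = names(snps)[j],
            chrom = as.character(seqnames(snps))[j], pos = start(snps)[j],
            rho = rho[best], nPooled = nPooled, pPooled = pPooled,
            nSnpsTested = length(cand),
            gatePassed = !is.na(pPooled) &&
                pPooled * length(cand) < gate,
            rSe = rSe, nSe = nSe, rNse = rNse, nNse = nNse,
            upregAlleleSe = upreg(rSe), upregAlleleNse = upreg(rNse),
            stringsAsFactors = FALSE)
    }
    if (length(skipped))
        warning(length(skipped), " gene(s) with no SNP in the cis window: ",
                paste(utils::head(skipped, 5), collapse = ", "),
                if (length(skipped) > 5) ", ...")
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) res <- data.frame()
    rownames(res) <- NULL
    res
}
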