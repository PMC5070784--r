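#' @include AllClasses.R utils.R
NULL

#' Quantile normalization across samples
#'
#' Maps each sample's values to the mean order statistics across samples,
#' so all samples share one empirical distribution; ties within a sample
#' receive the mean of the tied target values. Thin wrapper over
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param m numeric matrix, features x samples.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2) {
        warning("single sample: quantile normalization is the identity")
        return(m)
    }
    if (nrow(m) == 1)          # single feature: one shared order statistic
        return(matrix(mean(m), 1, ncol(m), dimnames = dimnames(m)))
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

# Ties are broken by position (rows are in canonical sorted-individual
# order) so every column is an exact permutation of the rankit grid and
# hence exactly centered; with averaged ranks a tied column would not be.
.rankit <- function(x, offset = 0.5) {
    qnorm((rank(x, ties.method = "first") - offset) /
          (length(x) - 2 * offset + 1))
}

#' Within-individual fold changes, transformed to standard normal
#'
#' Builds the response phenotype of reQTL mapping from a raw paired-design
#' study: (1) quantile-normalize expression across samples; (2) for every
#' individual with both conditions, fold change = SE / NSE per gene, with
#' zeros replaced by the gene's minimum nonzero value over all samples
#' (both conditions pooled) so the ratio is defined; (3) natural log;
#' (4) per gene, rank-based inverse-normal (rankit) transform
#' \eqn{\Phi^{-1}((rank - 1/2)/n)}, yielding marginally standard-normal
#' columns. Individuals lacking either condition are excluded; genes that
#' are zero in every sample, or whose log fold changes are constant across
#' individuals (rank transform undefined), are dropped with a warning.
#'
#' @param study an \linkS4class{ExpressionStudy} on the raw scale.
#' @param logBase base of the fold-change log (default \code{exp(1)};
#'   the rank transform makes downstream association invariant to it).
#' @param rankOffset rankit offset: 0.5 (default) or 3/8 (Blom).
#' @return A \linkS4class{FoldChangeMatrix}; \code{fcZeroFlags} marks
#'   cells where either the SE or the NSE value was zero-substituted.
#' @export
computeFoldChange <- function(study, logBase = exp(1), rankOffset = 0.5) {
    info <- colData(study)
    qn <- quantileNormalize(exprMatrix(study))
    both <- intersect(info$individual[info$condition == "SE"],
                      info$individual[info$condition == "NSE"])
    if (length(both) < 2)
        stop("need >= 2 individuals with both conditions")
    both <- sort(both)
    seCol <- rownames(info)[match(paste(both, "SE"),
                                  paste(info$individual, info$condition))]
    nseCol <- rownames(info)[match(paste(both, "NSE"),
                                   paste(info$individual, info$condition))]

    allZero <- rowSums(qn != 0) == 0
    if (any(allZero))
        warning(sum(allZero), " gene(s) zero in all samples dropped")
    qn <- qn[!allZero, , drop = FALSE]
    pos <- qn
    pos[pos == 0] <- NA
    gmin <- apply(pos, 1, min, na.rm = TRUE)

    num <- qn[, seCol, drop = FALSE]
    den <- qn[, nseCol, drop = FALSE]
    flag <- num == 0 | den == 0
    num[num == 0] <- gmin[row(num)[num == 0]]
    den[den == 0] <- gmin[row(den)[den == 0]]
    lfc <- (base::log(num) - base::log(den)) / base::log(logBase)
    lfc <- t(lfc)                      # individuals x genes
    flag <- t(flag)
    rownames(lfc) <- rownames(flag) <- both

    const <- apply(lfc, 2, function(x) diff(range(x)) == 0)
    if (any(const))
        warning(sum(const),
                " gene(s) with constant log fold change dropped")
    lfc <- lfc[, !const, drop = FALSE]
    flag <- flag[, !const, drop = FALSE]
    vals <- vapply(seq_len(ncol(lfc)),
                   function(j) .rankit(lfc[, j], offset = rankOffset),
                   numeric(nrow(lfc)))
    vals <- matrix(vals, nrow = nrow(lfc), dimnames = dimnames(lfc))
    new("FoldChangeMatrix", values = vals, zeroFlag = flag,
        genes = rowRanges(study)[colnames(vals)])
}

#' Remove hidden structure from a fold-change matrix
#'
#' Residualizes each gene's transformed fold changes on known covariates
#' plus the top-\code{k} principal components of the fold-change matrix
#' itself (computed on the response directly, not on raw expression, so
#' the factors removed are those relevant to the within-individual
#' ratios), then re-applies the rankit transform per gene so columns
#' remain marginally standard normal.
#'
#' @param fc a \linkS4class{FoldChangeMatrix}.
#' @param k number of principal components to remove (default 15); must
#'   be smaller than the number of individuals. \code{k = n - 1} removes
#'   essentially all variance and triggers an overcorrection warning.
#' @param covariates optional numeric matrix, one row per individual of
#'   \code{fc}.
#' @return A \linkS4class{FoldChangeMatrix}.
#' @export
hiddenFactorResidualize <- function(fc, k = 15L, covariates = NULL) {
    V <- fcValues(fc)
    n <- nrow(V)
    if (k >= n) stop("k must be smaller than the number of individuals")
    if (k == 0 && is.null(covariates)) return(fc)
    if (k >= n - 1)
        warning("k = n - 1 leaves ~no residual variance (overcorrection)")
    X <- cbind(rep(1, n))
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
    if (k > 0) {
        pcs <- prcomp(V, center = TRUE, scale. = FALSE)$x
        kEff <- min(k, ncol(pcs))  # rank of V caps the removable factors
        X <- cbind(X, pcs[, seq_len(kEff), drop = FALSE])
    }
    resid <- t(as.matrix(lm.fit(X, V)$residuals))
    vals <- apply(t(resid), 2, .rankit)
    dimnames(vals) <- dimnames(V)
    new("FoldChangeMatrix", values = vals, zeroFlag = fcZeroFlags(fc),
        genes = fc@genes)
}

# Window dosages for one gene, in canonical (sorted-individual) order;
# missing genotypes are mean-imputed so the permutation algebra stays
# complete-data. Returns NULL when no SNP survives the window/MAF filter.
.windowDosages <- function(fc, genotypes, gene, windowBp, mafMin) {
    genes <- fc@genes
    g <- match(gene, names(genes))
    snps <- snpRanges(genotypes)
    inWin <- as.character(seqnames(snps)) ==
                 as.character(seqnames(genes))[g] &
             abs(start(snps) - start(genes)[g]) <= windowBp &
             mcols(snps)$maf > mafMin
    if (!any(inWin)) return(NULL)
    ids <- sort(intersect(rownames(fcValues(fc)), individuals(genotypes)))
    dos <- dosages(genotypes)
    rownames(dos) <- individuals(genotypes)
    D <- dos[ids, inWin, drop = FALSE]
    for (j in seq_len(ncol(D))) {
        mis <- is.na(D[, j])
        if (any(mis)) D[mis, j] <- mean(D[, j], na.rm = TRUE)
    }
    keep <- apply(D, 2, function(x) stats::var(x) > 0)
    if (!any(keep)) return(NULL)
    list(D = D[, keep, drop = FALSE], ids = ids,
        snps = snps[inWin][keep])
}

#' Map cis-response-eQTLs by per-SNP regression of fold changes
#'
#' For each gene, regresses the transformed fold change on ALT dosage for
#' every SNP within \code{windowBp} of the TSS with MAF above
#' \code{mafMin} (simple linear model, two-sided t p-value). The SNP with
#' the smallest p-value per gene is flagged \code{best}; constant-dosage
#' SNPs are skipped.
#'
#' @param fc a \linkS4class{FoldChangeMatrix} (already residualized if
#'   desired; see \code{\link{hiddenFactorResidualize}}).
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param windowBp,mafMin cis window and MAF filter (defaults 1e6, 0.05).
#' @return data.frame with columns \code{gene}, \code{snp}, \code{chrom},
#'   \code{pos}, \code{slope}, \code{p}, \code{best}. Genes with no
#'   eligible SNP are skipped with a warning.
#' @export
mapReqtl <- function(fc, genotypes, windowBp = 1e6, mafMin = 0.05) {
    out <- list()
    skipped <- character(0)
    for (gene in colnames(fcValues(fc))) {
        w <- .windowDosages(fc, genotypes, gene, windowBp, mafMin)
        if (is.null(w)) { skipped <- c(skipped, gene); next }
        y <- fcValues(fc)[w$ids, gene]
        r <- colCorWith(y, w$D)
        n <- length(y)
        slope <- r * stats::sd(y) / apply(w$D, 2, stats::sd)
        p <- corPvalue(r, rep(n, length(r)))
        ord <- order(p, -abs(r), start(w$snps), names(w$snps))
        df <- data.frame(gene = gene, snp = names(w$snps),
                         chrom = as.character(seqnames(w$snps)),
                         pos = start(w$snps), slope = slope, p = p,
                         best = FALSE, stringsAsFactors = FALSE)
        df$best[ord[1]] <- TRUE
        out[[gene]] <- df
    }
    if (length(skipped))
        warning(length(skipped), " gene(s) skipped: no SNP in window")
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame()
    rownames(res) <- NULL
    res
}

#' Permutation-based empirical p-value for the best reQTL per gene
#'
#' The nominal p-value of the best SNP per gene is biased by selection
#' over the window; its significance is therefore calibrated against the
#' null distribution of best-SNP p-values obtained by permuting the
#' individual labels of the fold-change vector (genotypes fixed). The
#' empirical p-value uses the add-one estimator
#' \eqn{(1 + \#\{p^{perm}_b \le p^{obs}\})/(B + 1)}, so it can never be
#' smaller than \eqn{1/(B+1)}. Permutations are drawn over the sorted
#' individual ids, making results invariant to input row order; each gene
#' consumes its own stretch of the seeded RNG stream in the (sorted) gene
#' order of \code{fc}.
#'
#' @inheritParams mapReqtl
#' @param nPerm number of label permutations (>= 1; at least 1000
#'   recommended).
#' @param seed integer seed.
#' @param genes genes to test (default: all columns of \code{fc}).
#' @return data.frame with columns \code{gene}, \code{snp}, \code{chrom},
#'   \code{pos}, \code{slope}, \code{pNominal}, \code{pEmpirical},
#'   \code{nPerm}.
#' @export
permutationPvalue <- function(fc, genotypes, nPerm = 1000L, seed = 1L,
                              windowBp = 1e6, mafMin = 0.05,
                              genes = colnames(fcValues(fc))) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    set.seed(stageSeed(seed, "permutation"))
    out <- list()
    for (gene in sort(genes)) {
        w <- .windowDosages(fc, genotypes, gene, windowBp, mafMin)
        if (is.null(w)) next
        y <- fcValues(fc)[w$ids, gene]
        n <- length(y)
        r <- colCorWith(y, w$D)
        p <- corPvalue(r, rep(n, length(r)))
        bestIdx <- order(p, -abs(r), start(w$snps), names(w$snps))[1]
        pObs <- p[bestIdx]
        P <- vapply(seq_len(nPerm), function(b) sample.int(n),
                    integer(n))
        Yperm <- matrix(y[P], nrow = n)
        Rperm <- suppressWarnings(cor(w$D, Yperm))
        Pperm <- matrix(corPvalue(as.vector(abs(Rperm)),
                                  rep(n, length(Rperm))),
                        nrow = nrow(Rperm))
        bestPerm <- apply(Pperm, 2, min)
        pEmp <- (1 + sum(bestPerm <= pObs)) / (nPerm + 1)
        out[[gene]] <- data.frame(
            gene = gene, snp = names(w$snps)[bestIdx],
            chrom = as.character(seqnames(w$snps))[bestIdx],
            pos = start(w$snps)[bestIdx],
            slope = (r * stats::sd(y) /
                     apply(w$D, 2, stats::sd))[bestIdx],
            pNominal = pObs, pEmpirical = pEmp, nPerm = as.integer(nPerm),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame()
    rownames(res) <- NULL
    res
}
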