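#' @include AllClasses.R
NULL

#' Seasonal radiation summaries from monthly values
#'
#' Summer radiation is the mean over June/July/August for populations at
#' nonnegative latitude and December/January/February for southern
#' populations; winter radiation averages the opposite triplet. Months are
#' indexed 1-12 with January = 1; latitude exactly 0 is treated as
#' northern.
#'
#' @param monthly numeric vector of 12 monthly values, or a matrix with
#'   one row per population and 12 columns.
#' @param latitude latitude in degrees (vectorized over rows for matrix
#'   input).
#' @return For vector input, named numeric \code{c(summer=, winter=)};
#'   for matrix input, a matrix with columns \code{summer}, \code{winter}.
#' @examples
#' seasonalRadiation(c(rep(100, 5), 300, 310, 320, rep(100, 4)), 45)
#' @export
seasonalRadiation <- function(monthly, latitude) {
    if (is.matrix(monthly)) {
        if (ncol(monthly) != 12L)
            stop("monthly must have 12 columns")
        stopifnot(length(latitude) == nrow(monthly))
        out <- t(vapply(seq_len(nrow(monthly)), function(i)
            seasonalRadiation(monthly[i, ], latitude[i]), numeric(2)))
        rownames(out) <- rownames(monthly)
        return(out)
    }
    if (length(monthly) != 12L)
        stop("exactly 12 monthly values required, got ", length(monthly))
    if (anyNA(monthly))
        stop("missing months at indices: ",
             paste(which(is.na(monthly)), collapse = ", "))
    jja <- mean(monthly[6:8])
    djf <- mean(monthly[c(12, 1, 2)])
    if (latitude >= 0) c(summer = jja, winter = djf)
    else c(summer = djf, winter = jja)
}

#' Standardize an environmental variable across populations
#'
#' Centers to mean 0 and scales to sample standard deviation 1 — the scale
#' on which environment-allele-frequency association statistics are
#' computed, so slopes are comparable across variables.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return standardized vector.
#' @export
standardizeEnv <- function(values) {
    if (length(unique(values[!is.na(values)])) < 2)
        stop("cannot standardize a constant vector")
    (values - mean(values)) / stats::sd(values)
}

#' Per-regional-group correlation between radiation and allele frequency
#'
#' Spearman's rho between an environmental variable and the focal allele
#' frequency, computed separately within each regional group of the
#' panel. Consistent signs across regions indicate that the cline is not
#' an artifact of one continental gradient. Groups with fewer than
#' \code{minPops} populations are reported untestable; groups in which
#' either variable is constant are reported with \code{rho = NA}
#' (undefined by constancy).
#'
#' @param panel a \linkS4class{PopulationPanel}.
#' @param env per-population environmental values in panel row order
#'   (default: winter radiation derived from the panel climate).
#' @param minPops minimum populations per testable group (default 3).
#' @return data.frame: \code{group}, \code{rho}, \code{nPopulations},
#'   \code{nIndividuals}, \code{testable}.
#' @export
regionalCorrelations <- function(panel, env = NULL, minPops = 3L) {
    pops <- panelPopulations(panel)
    if (is.null(env)) {
        sr <- seasonalRadiation(panelClimate(panel), pops$latitude)
        env <- sr[, "winter"]
    }
    stopifnot(length(env) == nrow(pops))
    rows <- lapply(sort(unique(pops$group)), function(g) {
        sel <- pops$group == g
        nP <- sum(sel)
        testable <- nP >= minPops
        rho <- NA_real_
        if (testable)
            rho <- suppressWarnings(
                cor(env[sel], pops$freq[sel], method = "spearman"))
        data.frame(group = g, rho = rho, nPopulations = nP,
                   nIndividuals = sum(pops$n[sel]), testable = testable,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}

#' Empirical p-value of a focal statistic against a background
#'
#' Ranks a focal per-SNP adaptation statistic (e.g. an externally computed
#' Bayes factor, or the built-in \code{\link{clineStatistic}}) within the
#' distribution of the same statistic over a background SNP set, with the
#' add-one correction:
#' \eqn{p = (1 + \#\{bg \ge focal\})/(N + 1)}. Invariant to monotone
#' transforms of the statistic.
#'
#' @param focal scalar statistic of the SNP of interest.
#' @param background numeric vector of background statistics (nonempty).
#' @param largerIsStronger if FALSE the inequality is reversed.
#' @return empirical p-value in \eqn{(0, 1]}.
#' @export
empiricalPvalue <- function(focal, background, largerIsStronger = TRUE) {
    background <- background[!is.na(background)]
    if (length(background) == 0) stop("background must be nonempty")
    hits <- if (largerIsStronger) sum(background >= focal)
            else sum(background <= focal)
    (1 + hits) / (length(background) + 1)
}

#' Per-SNP median over repeated runs of a stochastic statistic
#'
#' MCMC-based adaptation statistics can be unstable run to run; the
#' conventional stabilization is the per-SNP median over repeated runs.
#'
#' @param runs a numeric matrix (SNPs x runs), or a data.frame with
#'   columns \code{snp}, \code{value}, \code{run}.
#' @return named numeric vector of per-SNP medians.
#' @export
medianOfRuns <- function(runs) {
    if (is.data.frame(runs)) {
        need <- c("snp", "value", "run")
        if (!all(need %in% names(runs)))
            stop("data.frame input needs columns snp, value, run")
        sets <- split(runs$snp, runs$run)
        ref <- sort(unique(sets[[1]]))
        same <- vapply(sets, function(s)
            identical(sort(unique(s)), ref), logical(1))
        if (!all(same)) stop("unequal SNP sets across runs")
        out <- tapply(runs$value, runs$snp, stats::median)
        return(stats::setNames(as.vector(out[ref]), ref))
    }
    m <- as.matrix(runs)
    if (ncol(m) < 1) stop("at least one run required")
    apply(m, 1, stats::median)
}

#' Built-in environmental cline statistic
#'
#' The absolute pooled Spearman correlation between a standardized
#' environmental variable and a SNP's allele frequencies across all
#' populations. A model-free stand-in for external
#' environment-association statistics, usable for both the focal SNP and
#' the background set so that \code{\link{empiricalPvalue}} compares like
#' with like. Returns NA for frequency vectors that are constant across
#' populations (correlation undefined by constancy).
#'
#' @param env per-population environmental values.
#' @param freq numeric vector of per-population frequencies, or a matrix
#'   SNPs x populations.
#' @return |rho| per SNP (vector input: scalar).
#' @export
clineStatistic <- function(env, freq) {
    envZ <- standardizeEnv(env)
    one <- function(f) {
        if (length(unique(f)) < 2) return(NA_real_)
        abs(suppressWarnings(cor(envZ, f, method = "spearman")))
    }
    if (is.matrix(freq)) apply(freq, 1, one) else one(freq)
}
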