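#' @include AllClasses.R
NULL

# Stage-specific RNG streams are derived from the single user seed so that
# (a) every generator/stage is individually reproducible and (b) running
# stages in a different order cannot silently change results. Derivation:
# seed * 7919 + <stage offset>, reduced mod 2^31 - 1.
.stageOffsets <- c(design = 101L, genotypes = 211L, expression = 307L,
                   ase = 401L, population = 503L, permutation = 601L,
                   pipeline = 701L)

stageSeed <- function(seed, stage) {
    off <- .stageOffsets[[stage]]
    as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Beta-binomial sampler parameterized by mean `prob` and overdispersion
# rho in [0,1); rho = 0 degenerates to the binomial.
rbetabinom <- function(n, size, prob, rho) {
    if (rho == 0) return(rbinom(n, size, prob))
    a <- prob * (1 - rho) / rho
    b <- (1 - prob) * (1 - rho) / rho
    rbinom(n, size, rbeta(n, a, b))
}

# Two-sided p-value of a (Pearson or rank) correlation via the asymptotic
# t approximation on n - 2 df. r at the +/-1 boundary maps to p = 0.
corPvalue <- function(r, n) {
    p <- rep(NA_real_, length(r))
    ok <- !is.na(r) & n > 2
    rr <- pmin(pmax(r[ok], -1), 1)
    tt <- abs(rr) * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.eps))
    p[ok] <- 2 * pt(tt, n[ok] - 2, lower.tail = FALSE)
    p[ok][abs(rr) >= 1] <- 0
    p
}

# Pairwise-complete Pearson correlation of a vector against matrix columns.
colCorWith <- function(y, X) {
    suppressWarnings(as.vector(cor(y, X, use = "pairwise.complete.obs")))
}
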