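---
title: "Mapping exposure-dependent cis-regulatory variants with exposeQTL"
author: "exposeQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping exposure-dependent cis-regulatory variants with exposeQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposeQTL)
```

## The problem

A cis-eQTL is a variant whose genotype associates with the expression of
a nearby gene. When the strength of that association depends on an
environmental exposure — here, paired sun-exposed (SE) and
non-sun-exposed (NSE) skin samples from the same donors — the variant is
a gene-by-environment (GxE) regulatory variant. Detecting such variants
naively, by mapping eQTLs separately per condition and comparing
significance, is unreliable: the strongest eQTL selected in one group
carries an inflated effect estimate there (the winner's curse), and a
difference in per-group significance can reflect nothing more than a
difference in power.

exposeQTL implements three mutually reinforcing discovery arms that
avoid these pitfalls, plus a synthetic-data module that generates
studies with exactly the statistical structure the analysis assumes, so
every stage can be calibrated end to end.

## Arm 1: the effect-size test with ASE validation

**Best-eQTL selection.** For each gene, `selectBestEqtl()` tests every
SNP within 1 Mb of the TSS (MAF > 0.05) by Spearman correlation between
ALT dosage and expression across *all samples pooled over conditions*,
keeping the SNP with the largest $|\rho|$. Selection on pooled data is
what removes the winner's curse: neither condition is favored, so the
per-condition effect estimates of the selected SNP are not biased
upward in either group. A within-gene Bonferroni gate
(`pPooled * nSnps < gate`) restricts downstream testing to genes with a
credible eQTL at all. Ties in $|\rho|$ (e.g. SNPs in perfect LD) are
broken by smaller genomic position, then lexicographic SNP id — an
arbitrary but deterministic repository convention.

**Effect-size test.** Per condition, the Pearson correlation $r$
between dosage and (residualized log) expression is Fisher-transformed,
$z = \tfrac12\log\frac{1+r}{1-r}$, and the difference is standardized:

$$t = \frac{z_{SE} - z_{NSE}}{\sqrt{1/(n_{SE}-3) + 1/(n_{NSE}-3)}},$$

which is standard normal under equal population correlations. We report
two-sided p-values throughout — the conservative choice when no
direction is predicted in advance. Correlations of exactly $\pm 1$
(which noise-free synthetic fixtures legitimately produce) are clamped
to $\pm(1-10^{-12})$ with a warning rather than treated as errors.

**Differential ASE.** Allele-specific expression is the within-sample
read ratio of the two haplotypes at a gene,
$ASE = a_1/(a_1 + a_2)$ with allele 1 the haplotype in phase with the
designated eQTL allele. `computeAse()` enforces two filters before the
ratio is formed: sites with zero reads on one allele and at least 15
reads in total are discarded as mono-allelic artifacts (the 15-read
cutoff is our convention for "deep enough that true biallelic
expression would have shown the second allele"), and aggregated
observations with fewer than 3 reads are dropped. The differential test
(`differentialAseTest()`) is Welch's two-sample t-test between SE and
NSE heterozygotes at the eQTL; Welch rather than pooled-variance
because group sizes and variances differ by construction. A gene is
testable only when each of SE-hom, SE-het, NSE-hom and NSE-het has at
least 5 observations. Because the ASE contrast is within-individual, it
is statistically independent of the across-individual effect-size test
under the null — a property the acceptance suite verifies by
simulation — which is what makes it a genuine validation rather than a
re-test of the same signal.

Phasing between the eQTL and the exonic sites is taken as given in the
input table; the simulator models imperfect phasing as a configurable
switch-error rate (`phaseError`), which dilutes ASE signal toward 1/2
and is one reason concordance between the arms underestimates truth.

**Concordance and combination.** `isConcordant()` requires (1) the same
condition to show the stronger effect in both tests — measured by
$|z|$ on the eQTL side and $|\bar{ASE} - 1/2|$ of the heterozygote
group on the ASE side (the ASE-side magnitude measure is our choice;
any monotone measure of imbalance would do) — and (2) the same
upregulating allele. `combinedDiscovery()` then applies
Benjamini-Hochberg FDR to the differential-ASE p-values *within* the
set of genes that are concordant and nominally significant
(effect-size p < 0.05). The q-values are therefore conditional on the
filter; they control FDR within the filtered set, which is the
quantity of interest for the reported discoveries.
`concordanceBinomialTest()` provides the companion enrichment check:
an exact two-sided binomial test of the concordant fraction against
the background concordance computed from all genes with both tests
defined (not a fixed constant).

## Arm 2: response-eQTL (reQTL) mapping

The second arm asks a within-individual question: does any local SNP
associate with each donor's expression *ratio* between conditions?
`computeFoldChange()` builds the phenotype: quantile normalization
across samples (via `limma::normalizeQuantiles`), per-individual fold
change SE/NSE with zeros replaced by the gene's minimum nonzero value
across all samples (both conditions pooled), natural log, then a
per-gene rank-based inverse-normal (rankit) transform
$\Phi^{-1}((\mathrm{rank}-\tfrac12)/n)$. The log base is configurable
but irrelevant after rank transformation; the rankit offset defaults
to 1/2 with Blom's 3/8 available. Rank ties — which quantile
normalization can create — are broken by position in the canonical
sorted-individual order, so every column is an exact permutation of
the rankit grid and exactly centered; averaging tied ranks would leave
tied columns off-center.

`hiddenFactorResidualize()` removes known covariates plus the top-k
principal components of the fold-change matrix itself (default k = 15),
computed on the ratios directly rather than on raw expression so that
the factors removed are the ones confounding the within-individual
contrast; columns are re-rankited afterwards. `mapReqtl()` fits a
simple linear regression of the transformed fold change on dosage for
every SNP in the 1 Mb window (MAF > 0.05), and
`permutationPvalue()` calibrates the best SNP per gene against the
null distribution of best-SNP p-values under permutation of the
individual labels of the fold-change vector (genotypes fixed; at least
1000 permutations), using the add-one estimator
$(1 + \#\{p^{perm} \le p^{obs}\})/(B+1)$, whose floor is $1/(B+1)$.
Permutations are drawn over sorted individual ids so results are
invariant to input row order. Missing genotypes are mean-imputed
within the window for the permutation algebra; gene-level FDR over
empirical p-values is available through `bhFdr()`.

## Arm 3: environmental allele-frequency association

If an exposure-dependent regulatory allele has been adaptive, its
frequency should track the relevant environmental gradient across
populations. `seasonalRadiation()` builds the exposure variables from
monthly radiation values: summer averages June-August north of the
equator and December-February south of it, winter the opposite months;
latitude 0 is treated as northern. Values are standardized
(`standardizeEnv()`) before association. The module deliberately does
not reimplement covariance-aware Bayesian association machinery: it
accepts any externally computed per-SNP statistic (stabilized across
stochastic runs by `medianOfRuns()`), and offers a built-in model-free
alternative, `clineStatistic()` — the absolute pooled Spearman
correlation between standardized environment and allele frequency.
Significance comes from `empiricalPvalue()`: the focal statistic is
ranked within the same statistic computed on a background SNP set
(add-one correction, ties counted as exceedances). Because the
empirical p-value depends only on ranks it is invariant to monotone
transforms of the statistic. `regionalCorrelations()` reports the
per-regional-group Spearman correlations that show whether a cline is
consistent across continents or driven by a single gradient; groups
with fewer than 3 populations are untestable, and constant frequencies
yield an explicit undefined (NA) rather than a number.

## The synthetic-data module

`SimulationConfig()` fixes the study the generators emulate. For
individual $i$, condition $c$, gene $g$ with causal dosage $d_{ig}$:

$$y = \mu_g + u_i + \beta_c d_{ig} + \varepsilon,\qquad
u_i \sim N(0, \sigma_{ind}^2),\ \varepsilon \sim N(0, \sigma^2),$$

with stored expression $e^y$ (nonnegative, RPKM-like; downstream
stages re-log). Genotypes are Hardy-Weinberg at a frequency uniform in
`mafRange`, one gene per chromosome so cis windows never overlap, and
the middle of the `nSnpsPerGene` SNPs is causal. Allele-specific
counts are Poisson total depth with beta-binomial allele-1 counts,
mean $e^{\beta_c}/(1+e^{\beta_c})$ for eQTL heterozygotes and 1/2 for
homozygotes — the same single causal effect thus drives both the
across-individual eQTL signal and the within-individual imbalance,
which is the property the concordance rules exploit.

Defaults (150 donors, all paired, $\beta_{SE} = 0.8$,
$\beta_{NSE} = 0$, noise and individual s.d. 0.5, depth 50,
overdispersion 0.05) describe a paired skin study of realistic size:
147 donors contributed both conditions in the motivating design, and
a latent effect of 0.8 s.d. per allele with unit-variance noise
corresponds to a strong but unexceptional cis-eQTL. The population
generator places populations on a latitudinal radiation gradient and
draws the focal frequency from a logistic cline in standardized winter
radiation plus logit-scale drift, with neutral background SNPs
drifting around environment-free means.

What the generators do **not** emulate: linkage disequilibrium from
real reference panels (SNPs are independent by default), read-level
artifacts (mapping bias, duplicate reads — the count tables start
where read processing ends), population covariance structure beyond
latitude bands, and selection models richer than the logistic cline.
Passing tests therefore demonstrate correctness and calibration of the
statistical machinery under the assumed generative model, not
robustness to every failure mode of real data.

## Numerical and design choices

- **Calibration experiments use a between-individual design.** The
  effect-size test treats $z_{SE}$ and $z_{NSE}$ as independent. When
  the same donors contribute both conditions *and* the shared donor
  effect $u_i$ is large, the two sample correlations co-fluctuate and
  the test becomes conservative. `calibrateEffectSizeTest()` therefore
  assigns distinct donors to each condition, the regime the test is
  designed for; the paired design is still the right one for the ASE
  and reQTL arms, which is precisely why the package carries all
  three.
- **Problem sizes.** The shipped calibration studies use $10^4$
  replicate genes for type-I error, 1000 genes for the independence
  experiment, 50 replicate 200-gene studies for combined-discovery
  operating characteristics, and 500 genes x 1000 permutations for
  reQTL validity — sizes at which the binomial/KS assertions have
  comfortable margins while a full run stays in the minutes range on
  one core.
- **Seeds.** Every generator and the permutation engine derive
  per-stage streams from one user seed
  (`seed * 7919 + stage offset, mod 2^31 - 1`), so stages are
  individually reproducible and whole runs are bit-identical.
- **Degenerate inputs** are contracts, not crashes: genes with empty
  cis windows are skipped with a warning; an untestable ASE gene is a
  flagged row, not an exception; a constant fold-change column is
  dropped; a constant frequency vector yields NA with the reason
  recorded; an empty ASE table degrades the pipeline to
  "all genes ASE-untestable".
- **Open choices resolved here:** empirical p-values use the add-one
  estimator with ties counted as exceedances; fold changes use natural
  log; permutations shuffle fold-change labels with genotypes fixed;
  the background concordance fraction is computed over all genes with
  both tests defined.

## Interfaces

The package is driven from R: `simulateStudy()` and the writers
produce a complete study on disk (VCF v4.2 with phased GT; TSVs for
expression, metadata, genes, ASE counts, population panel), and
`runPipeline(PipelineConfig(...))` executes both discovery arms plus
the optional environmental stage, writing stage outputs and a JSON
manifest with config, seed and checksums. The exported stage functions
compose identically to the pipeline — the test suite asserts that the
pipeline's discovery set equals a stage-by-stage run. No shell entry
point is shipped; functions plus the reproducibility script
(`scripts/acceptance.R`) are the intended surface for an analysis
package of this kind.

## Worked example

```{r example, eval = FALSE}
cfg <- SimulationConfig(nIndividuals = 150, nGenes = 50, seed = 1)
sim <- simulateStudy(cfg)
hits <- selectBestEqtl(residualizeExpression(sim$study),
                       sim$genotypes, gate = 1)
es <- cbind(hits, effectSizeTest(hits$rSe, hits$rNse,
                                 hits$nSe, hits$nNse))
da <- differentialAseTest(computeAse(sim$ase),
                          eqtlGenotypeClasses(sim$genotypes, es))
disc <- combinedDiscovery(es, da)
table(significant = disc$significant, concordant = disc$concordant)
```

## Known limitations

The effect-size test inherits the Fisher-z normal approximation
(adequate for n in the tens and above; the constructor refuses
n < 4). BH q-values in the combined procedure are conditional on the
concordance/nominal filter. The built-in cline statistic ignores
shared population ancestry, so its empirical p-values lean entirely on
the background set to absorb that structure — with a small or
unrepresentative background they should not be over-read. ASE power
depends on read depth and het counts; the group-size and read filters
trade sensitivity for stability exactly as the thresholds state.
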