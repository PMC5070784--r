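#' @include AllClasses.R io.R vcf.R
NULL

#' Configuration of the end-to-end discovery pipeline
#'
#' Bundles input paths and analysis thresholds. Defaults are the values
#' used throughout the package: a 1 Mb cis window, MAF > 0.05, nominal
#' effect-size threshold 0.05, combined FDR 0.05, 15 hidden factors, 1000
#' permutations, >= 3 reads per ASE observation and >= 5 observations per
#' ASE group.
#'
#' @param vcf,expr,meta,genes input paths (VCF genotypes; expression,
#'   sample-metadata and gene-annotation TSVs).
#' @param ase path of the allele-specific count TSV, or NA to skip the
#'   ASE arm (all genes then ASE-untestable).
#' @param panel,climate,background optional population-panel paths; NA
#'   skips the environmental stage.
#' @param outDir output directory (created if absent).
#' @param windowBp,mafMin,gate,alphaNominal,fdr,kHidden,nPerm,minReads,
#'   minGroupObs analysis thresholds (see the stage functions).
#' @param seed integer seed from which all stage seeds derive.
#' @return a validated \code{PipelineConfig} object.
#' @export
PipelineConfig <- function(vcf, expr, meta, genes, ase = NA_character_,
                           panel = NA_character_,
                           climate = NA_character_,
                           background = NA_character_,
                           outDir = ".", windowBp = 1e6, mafMin = 0.05,
                           gate = 0.05, alphaNominal = 0.05, fdr = 0.05,
                           kHidden = 15L, nPerm = 1000L, minReads = 3L,
                           minGroupObs = 5L, seed = 1L) {
    stopifnot(windowBp > 0, mafMin >= 0, mafMin < 0.5,
              gate > 0, gate <= 1, alphaNominal > 0, alphaNominal <= 1,
              fdr > 0, fdr <= 1, kHidden >= 0, nPerm >= 1, minReads >= 1,
              minGroupObs >= 1)
    for (p in c(vcf, expr, meta, genes)) {
        if (!file.exists(p)) stop("input file not found: ", p)
    }
    structure(list(vcf = vcf, expr = expr, meta = meta, genes = genes,
                   ase = ase, panel = panel, climate = climate,
                   background = background, outDir = outDir,
                   windowBp = windowBp, mafMin = mafMin, gate = gate,
                   alphaNominal = alphaNominal, fdr = fdr,
                   kHidden = as.integer(kHidden),
                   nPerm = as.integer(nPerm),
                   minReads = as.integer(minReads),
                   minGroupObs = as.integer(minGroupObs),
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Run the full exposure-dependent cis-regulation pipeline
#'
#' Executes both discovery arms on one set of inputs:
#' \enumerate{
#'   \item effect-size arm — residualize (log + mean-center), select the
#'     best pooled eQTL per gene, effect-size test, gene-level ASE,
#'     differential-ASE test among eQTL heterozygotes, concordance and
#'     combined FDR;
#'   \item response arm — within-individual fold changes, hidden-factor
#'     residualization, per-SNP reQTL mapping and permutation-based
#'     empirical p-values (gene-level FDR on empirical p via
#'     \code{\link{bhFdr}});
#'   \item (optional) environmental arm — seasonal radiation,
#'     standardization, the built-in cline statistic for significant
#'     genes' eQTLs against the background SNP panel, empirical p-values
#'     and per-region Spearman correlations.
#' }
#' All stage outputs are written as TSV under \code{outDir} together with
#' a JSON run manifest (config, seed, package version, output checksums).
#' Reruns with identical config and inputs are bit-identical.
#'
#' @param config a \code{\link{PipelineConfig}}.
#' @return invisibly, a list with elements \code{hits},
#'   \code{effectSize}, \code{diffAse}, \code{seEqtls}, \code{reqtl},
#'   \code{adaptation} (NULL when skipped) and \code{manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    withStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    genotypes <- withStage("read_vcf", readGenotypeVcf(config$vcf))
    study <- withStage("read_expression",
        readExpressionStudy(config$expr, config$meta, config$genes))

    resid <- withStage("residualize", residualizeExpression(study))
    hits <- withStage("select_best_eqtl",
        suppressWarnings(selectBestEqtl(resid, genotypes,
            windowBp = config$windowBp, mafMin = config$mafMin,
            gate = config$gate)))
    es <- cbind(hits, withStage("effect_size_test",
        effectSizeTest(hits$rSe, hits$rNse, hits$nSe, hits$nNse)))

    if (!is.na(config$ase)) {
        aseCounts <- withStage("read_ase", readAseCounts(config$ase))
        aseObs <- withStage("compute_ase",
            computeAse(aseCounts, minReads = config$minReads))
    } else {
        aseObs <- data.frame(individual = character(0),
                             gene = character(0),
                             condition = character(0), ase = numeric(0),
                             totalReads = integer(0))
    }
    classes <- withStage("eqtl_classes",
        eqtlGenotypeClasses(genotypes, es))
    da <- withStage("differential_ase",
        differentialAseTest(aseObs, classes,
                            minGroupObs = config$minGroupObs))
    if (nrow(da) == 0)
        da <- data.frame(gene = es$gene, nSeHom = 0L, nSeHet = 0L,
                         nNseHom = 0L, nNseHet = 0L, meanSeHet = NA_real_,
                         meanNseHet = NA_real_, meanSeHom = NA_real_,
                         meanNseHom = NA_real_, pDiff = NA_real_,
                         strongerGroup = NA_character_,
                         direction = NA_real_, testable = FALSE)
    seEqtls <- withStage("combined_discovery",
        combinedDiscovery(es, da, alphaNominal = config$alphaNominal,
                          fdr = config$fdr))

    fc <- withStage("fold_change",
        suppressWarnings(computeFoldChange(study)))
    k <- min(config$kHidden, nrow(fcValues(fc)) - 2L)
    if (k > 0)
        fc <- withStage("hidden_factors",
            suppressWarnings(hiddenFactorResidualize(fc, k = k)))
    reqtl <- withStage("permutation",
        permutationPvalue(fc, genotypes, nPerm = config$nPerm,
                          seed = config$seed,
                          windowBp = config$windowBp,
                          mafMin = config$mafMin))
    if (nrow(reqtl))
        reqtl$qEmpirical <- bhFdr(reqtl$pEmpirical)

    adaptation <- NULL
    if (!is.na(config$panel)) {
        panel <- withStage("read_panel",
            readPopulationPanel(config$panel, config$climate,
                                config$background))
        pops <- panelPopulations(panel)
        sr <- seasonalRadiation(panelClimate(panel), pops$latitude)
        stat <- clineStatistic(sr[, "winter"], pops$freq)
        bgStat <- clineStatistic(sr[, "winter"], panelBackground(panel))
        adaptation <- data.frame(
            snp = "focal", statistic = stat,
            pEmpirical = empiricalPvalue(stat, bgStat),
            stringsAsFactors = FALSE)
        attr(adaptation, "regional") <- regionalCorrelations(panel)
    }

    paths <- c(hits = "hits.tsv", effect_size = "effect_size.tsv",
               ase_observations = "ase_observations.tsv",
               diff_ase = "diff_ase.tsv", se_eqtls = "se_eqtls.tsv",
               reqtl = "reqtl.tsv")
    outs <- file.path(config$outDir, paths)
    names(outs) <- names(paths)
    .writeTsv(hits, outs[["hits"]])
    .writeTsv(es, outs[["effect_size"]])
    .writeTsv(aseObs, outs[["ase_observations"]])
    .writeTsv(da, outs[["diff_ase"]])
    .writeTsv(seEqtls, outs[["se_eqtls"]])
    .writeTsv(reqtl, outs[["reqtl"]])
    if (!is.null(adaptation)) {
        adPath <- file.path(config$outDir, "adaptation.tsv")
        .writeTsv(adaptation, adPath)
        outs <- c(outs, adaptation = adPath)
    }

    manifest <- list(
        package = "exposeQTL",
        version = as.character(utils::packageVersion("exposeQTL")),
        seed = config$seed,
        config = unclass(config),
        outputs = as.list(structure(basename(outs), names = names(outs))),
        checksums = as.list(tools::md5sum(outs)))
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(hits = hits, effectSize = es, diffAse = da,
                   seEqtls = seEqtls, reqtl = reqtl,
                   adaptation = adaptation, manifest = manifestPath))
}
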