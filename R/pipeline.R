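#' Pipeline configuration
#'
#' Collects every option of the end-to-end analysis in one object. The QC
#' thresholds default to the standard PennCNV-workflow values (30 CNVs,
#' waviness 0.03, call rate 0.96, 10 probes, 1 probe per 20,000 bp) and
#' the phenotype fence to 2.5 SD; the FDR level defaults to 0.10 and the
#' resampling null to 100,000 replicates. All overrides are captured in
#' the config hash recorded in the provenance report.
#'
#' @param simulation a [simulationConfig()] describing the synthetic
#'   cohort (the pipeline's input generator).
#' @param loci locus definitions; default [defaultLoci()].
#' @param exclusionCodes an [exclusionCodeList()].
#' @param maxCnvs,maxWaviness,minCallRate,minProbes,minDensity CNV QC
#'   thresholds.
#' @param sdFence outlier fence in SDs.
#' @param q FDR level.
#' @param B null-distribution replicate count.
#' @param nComponents ICA component count.
#' @param overallFamilySize declared whole-brain family size (`NULL` =
#'   number of tests run).
#' @param seed analysis seed (covariance resampling / ICA).
#' @param regional fit the per-region association families.
#' @param residualize residualize regions before covariance analysis.
#' @return a classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           loci = defaultLoci(),
                           exclusionCodes = defaultExclusionCodes(),
                           maxCnvs = 30, maxWaviness = 0.03,
                           minCallRate = 0.96, minProbes = 10,
                           minDensity = 1 / 20000, sdFence = 2.5,
                           q = 0.10, B = 100000L, nComponents = 20L,
                           overallFamilySize = NULL, seed = 1L,
                           regional = TRUE, residualize = FALSE) {
    cfg <- list(simulation = simulation, loci = loci,
                exclusionCodes = exclusionCodes, maxCnvs = maxCnvs,
                maxWaviness = maxWaviness, minCallRate = minCallRate,
                minProbes = minProbes, minDensity = minDensity,
                sdFence = sdFence, q = q, B = as.integer(B),
                nComponents = as.integer(nComponents),
                overallFamilySize = overallFamilySize,
                seed = as.integer(seed), regional = regional,
                residualize = residualize)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar options map directly onto [pipelineConfig()] arguments; the
#' `simulation` block maps onto [simulationConfig()] arguments; `loci`
#' may be a path to a locus JSON file.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim_args <- y$simulation %||% list()
    if (!is.null(sim_args$nCarriersPerLocus))
        sim_args$nCarriersPerLocus <- unlist(sim_args$nCarriersPerLocus)
    sim <- do.call(simulationConfig, sim_args)
    loci <- if (is.null(y$loci)) defaultLoci() else readLocusDefinitions(y$loci)
    extra <- y[setdiff(names(y), c("simulation", "loci"))]
    do.call(pipelineConfig, c(list(simulation = sim, loci = loci), extra))
}

# stable hash of the full configuration (md5 of its canonical JSON)
configHash <- function(config) {
    lj <- lapply(seq_along(config$loci), function(i) {
        md <- mcols(config$loci)[i, ]
        list(locus = md$locus, chrom = as.character(seqnames(config$loci))[i],
             start = start(config$loci)[i], end = end(config$loci)[i],
             dosage = md$dosage, category = md$category)
    })
    sim <- config$simulation
    canon <- list(simulation = list(
                      nNoncarriers = sim@nNoncarriers,
                      nCarriersPerLocus = as.list(sim@nCarriersPerLocus),
                      nExcludedByCodes = sim@nExcludedByCodes,
                      nFailSampleQc = sim@nFailSampleQc,
                      nPathogenic = sim@nPathogenic,
                      nRegions = sim@nRegions, measures = sim@measures,
                      meanShift = sim@meanShift,
                      factorLoading = sim@factorLoading,
                      noiseSd = sim@noiseSd,
                      covariateEffects = sim@covariateEffects,
                      outlierRate = sim@outlierRate,
                      callFailProbes = sim@callFailProbes,
                      callFailDensity = sim@callFailDensity,
                      seed = sim@seed),
                  loci = lj,
                  exclusionCodes = config$exclusionCodes,
                  options = config[setdiff(names(config),
                                           c("simulation", "loci",
                                             "exclusionCodes"))])
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(as.character(jsonlite::toJSON(canon, auto_unbox = TRUE,
                                             digits = NA, null = "null")), f)
    unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation, CNV QC and carrier
#' classification, diagnosis-code exclusion, outlier removal, dataset
#' assembly, the association families, and the structural covariance
#' comparison. Every stage's input/kept/excluded counts are recorded in a
#' provenance report, with the conservation property
#' `input = kept + excluded` at each stage. Fully deterministic given the
#' seeds in `config`.
#'
#' @param config a [pipelineConfig()].
#' @param outdir optional directory; when given, result tables
#'   (association TSV, z-matrices, integration indices, component
#'   weights, p-values), the provenance report and the exact
#'   configuration are written there.
#' @return list with elements `dataset` (the analysis
#'   [CorticalCohort-class]), `statuses`, `association`, `covariance`
#'   (see [compareGroups()]) and `provenance`.
#' @export
runPipeline <- function(config, outdir = NULL) {
    assertThat(inherits(config, "PipelineConfig"),
               "config must come from pipelineConfig()")
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    prov <- list(config_hash = configHash(config),
                 seeds = list(simulation = config$simulation@seed,
                              analysis = config$seed),
                 stages = list())
    note <- function(name, input, kept, excluded) {
        prov$stages[[name]] <<- list(input = input, kept = kept,
                                     excluded = excluded)
    }

    sc <- stage("simulate", simulateCohort(config$simulation))
    fx <- stage("simulate",
                simulateCnvFixtures(config$simulation, config$loci))
    cohort <- cohortData(sc)
    n0 <- ncol(cohort)
    note("simulate", n0, n0, 0L)

    statuses <- stage("classify", classifyParticipants(
        fx$calls, fx$sampleQc[, c("sample_id", "n_cnvs", "waviness",
                                  "call_rate")],
        config$loci, maxCnvs = config$maxCnvs,
        maxWaviness = config$maxWaviness, minCallRate = config$minCallRate,
        minProbes = config$minProbes, minDensity = config$minDensity))

    cd <- as.data.frame(colData(cohort))
    cd$participant_id <- colnames(cohort)
    codes <- stage("exclude_codes",
                   excludeByCodes(cd, config$exclusionCodes))
    code_excluded <- codes$participant_id[codes$excluded_code]
    note("exclude_codes", n0, n0 - length(code_excluded),
         length(code_excluded))

    n_qc <- sum(statuses$status == "excluded_qc")
    n_path <- sum(statuses$status == "excluded_pathogenic")
    n_in <- n0 - length(code_excluded)
    note("sample_qc", n_in, n_in - sum(statuses$status == "excluded_qc" &
             !statuses$sample_id %in% code_excluded),
         sum(statuses$status == "excluded_qc" &
             !statuses$sample_id %in% code_excluded))

    prepared <- stage("prepare", {
        x <- removeOutliers(cohort, k = config$sdFence)
        assembleDataset(x, statuses, codeExcluded = code_excluded)
    })
    gi <- prov$stages$sample_qc$kept
    note("pathogenic_and_assemble", gi, ncol(prepared), gi - ncol(prepared))
    prov$group_n <- metadata(prepared)$group_n
    prov$excluded_total <- list(codes = length(code_excluded),
                                sample_qc = n_qc, pathogenic = n_path)

    assoc <- stage("associate", runFamily(
        prepared, q = config$q,
        overallFamilySize = config$overallFamilySize,
        regional = config$regional))

    covar <- stage("covariance", compareGroups(
        prepared, B = config$B, k = config$nComponents,
        seed = config$seed, q = config$q,
        residualize = config$residualize))

    res <- list(dataset = prepared, statuses = statuses,
                association = assoc, covariance = covar,
                provenance = prov)
    if (!is.null(outdir)) writeResults(res, outdir)
    res
}

#' @rdname runPipeline
#' @param results the list returned by `runPipeline()`.
#' @export
writeResults <- function(results, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, name, ...)
        utils::write.table(x, file.path(outdir, name), sep = "\t",
                           quote = FALSE, ...)
    w(results$statuses, "carrier_status.tsv", row.names = FALSE)
    w(results$association, "association.tsv", row.names = FALSE)
    summary_json <- list()
    for (m in names(results$covariance)) {
        cm <- results$covariance[[m]]
        w(round(zMat(cm$carriers), 6), paste0("zmatrix_carriers_", m, ".tsv"))
        w(round(zMat(cm$noncarriers), 6),
          paste0("zmatrix_noncarriers_", m, ".tsv"))
        idx <- data.frame(region = names(integrationIndex(cm$carriers)),
                          carriers = integrationIndex(cm$carriers),
                          noncarriers = integrationIndex(cm$noncarriers),
                          p = cm$p$integration,
                          fdr_flag = cm$fdr$integration)
        w(idx, paste0("integration_", m, ".tsv"), row.names = FALSE)
        w(round(cm$weights, 6), paste0("ica_weights_", m, ".tsv"))
        comp <- data.frame(component = colnames(cm$componentValues),
                           t(cm$componentValues), p = cm$p$component,
                           fdr_flag = cm$fdr$component)
        w(comp, paste0("components_", m, ".tsv"), row.names = FALSE)
        summary_json[[m]] <- list(
            overall_carriers = overallValue(cm$carriers),
            overall_noncarriers = overallValue(cm$noncarriers),
            overall_p = cm$p$overall,
            n_gyrus_fdr = sum(cm$fdr$integration),
            n_component_fdr = sum(cm$fdr$component))
    }
    jsonlite::write_json(list(covariance = summary_json,
                              provenance = results$provenance),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outdir)
}
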