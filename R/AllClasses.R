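#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData colData<-
NULL

# ---------------------------------------------------------------------------
# CorticalCohort: regional morphometry + covariates for one analysis sample
# ---------------------------------------------------------------------------

#' CorticalCohort: regional cortical measures with participant covariates
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one or both morphometric assays (`thickness` in mm, `surface_area` in
#' mm^2) as regions x participants matrices, together with participant
#' covariates (age, sex, intracranial volume, assessment centre, group
#' label) in `colData`. Rows are Desikan-Killiany regions (see
#' [dkRegions()]); columns are participants.
#'
#' Missing values in the assays are permitted (they arise from outlier
#' removal, see [removeOutliers()]).
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @export
setClass("CorticalCohort", contains = "SummarizedExperiment")

setValidity("CorticalCohort", function(object) {
    msg <- character()
    bad <- setdiff(assayNames(object), corticalMeasures())
    if (length(bad))
        msg <- c(msg, paste0("unknown assay name(s): ",
                             paste(bad, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "region (row) names must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "participant (column) names must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CorticalCohort
#'
#' @param assays named list of numeric matrices (regions x participants);
#'   names must be among `corticalMeasures()`.
#' @param covariates data.frame or DataFrame of participant covariates, one
#'   row per participant, with a `participant_id` column (or rownames)
#'   matching the assay column names.
#' @return A [CorticalCohort-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("r", 1:3), c("a", "b")))
#' cc <- corticalCohort(list(thickness = m),
#'                      data.frame(participant_id = c("a", "b"),
#'                                 age = c(50, 60)))
#' dim(cc)
#' @export
corticalCohort <- function(assays, covariates = NULL) {
    assertThat(is.list(assays) && length(assays) > 0 &&
               !is.null(names(assays)), "'assays' must be a non-empty named list")
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        if ("participant_id" %in% names(covariates))
            rownames(covariates) <- covariates$participant_id
        assertThat(setequal(rownames(covariates), colnames(assays[[1]])),
                   "covariate rows do not match assay columns")
        covariates <- covariates[colnames(assays[[1]]), , drop = FALSE]
        cd <- DataFrame(covariates)
    } else {
        cd <- DataFrame(row.names = colnames(assays[[1]]))
    }
    se <- SummarizedExperiment(assays = assays, colData = cd)
    new("CorticalCohort", se)
}

#' @describeIn corticalCohort participant group labels (the `group` covariate,
#'   or NULL when absent).
#' @param x a CorticalCohort.
#' @export
cohortGroups <- function(x) {
    cd <- colData(x)
    if ("group" %in% colnames(cd)) as.character(cd$group) else NULL
}

#' @describeIn corticalCohort subset to participants whose `group` is in
#'   `groups`.
#' @param groups character vector of group labels to keep.
#' @export
subsetGroups <- function(x, groups) {
    g <- cohortGroups(x)
    assertThat(!is.null(g), "cohort has no 'group' covariate")
    x[, g %in% groups]
}

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' SimulationConfig: parameters of the synthetic-cohort generator
#'
#' Describes a synthetic cohort: how many non-carriers and how many carriers
#' of each CNV locus; how many participants are destined to drop out at each
#' quality-control stage (diagnosis-code exclusion, array sample QC,
#' pathogenic-CNV exclusion); and the generative model for the regional
#' measures. See [simulateCohort()] for the model itself.
#'
#' @slot nNoncarriers integer, number of CNV non-carriers.
#' @slot nCarriersPerLocus named integer vector, carriers per SCZ locus.
#' @slot nExcludedByCodes integer, participants given an excluding diagnosis
#'   code.
#' @slot nFailSampleQc integer, participants failing array sample QC.
#' @slot nPathogenic integer, carriers of a non-SCZ pathogenic CNV.
#' @slot nRegions integer, number of cortical regions (68 = D-K atlas).
#' @slot measures character, subset of `corticalMeasures()`.
#' @slot meanShift named list (by measure) of per-locus standardized carrier
#'   mean shifts (delta).
#' @slot factorLoading named list (by measure) of length-2 numeric vectors
#'   `c(carrier=, non_carrier=)` giving the latent-factor loading b.
#' @slot noiseSd positive numeric, residual SD on the standardized scale.
#' @slot covariateEffects named list (by measure) of coefficients for
#'   `c(age=, sex=, icv=, centre=)` on the standardized scale.
#' @slot outlierRate probability an assay value is replaced by an injected
#'   extreme value (mean +/- 6 SD).
#' @slot callFailProbes integer, fixture calls failing the probe-count filter.
#' @slot callFailDensity integer, fixture calls failing the density filter.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
    representation(nNoncarriers = "integer",
                   nCarriersPerLocus = "integer",
                   nExcludedByCodes = "integer",
                   nFailSampleQc = "integer",
                   nPathogenic = "integer",
                   nRegions = "integer",
                   measures = "character",
                   meanShift = "list",
                   factorLoading = "list",
                   noiseSd = "numeric",
                   covariateEffects = "list",
                   outlierRate = "numeric",
                   callFailProbes = "integer",
                   callFailDensity = "integer",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnts <- c(object@nNoncarriers, object@nCarriersPerLocus,
              object@nExcludedByCodes, object@nFailSampleQc,
              object@nPathogenic, object@callFailProbes,
              object@callFailDensity)
    if (any(is.na(cnts)) || any(cnts < 0L))
        msg <- c(msg, "all counts must be non-negative")
    if (is.na(object@nRegions) || object@nRegions < 1L)
        msg <- c(msg, "nRegions must be positive")
    if (!length(object@measures) ||
        !all(object@measures %in% corticalMeasures()))
        msg <- c(msg, paste("measures must be among:",
                            paste(corticalMeasures(), collapse = ", ")))
    if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    for (m in object@measures) {
        b <- object@factorLoading[[m]]
        if (is.null(b) || !all(c("carrier", "non_carrier") %in% names(b)))
            msg <- c(msg, sprintf(
                "factorLoading$%s must name 'carrier' and 'non_carrier'", m))
    }
    if (object@outlierRate < 0 || object@outlierRate >= 1)
        msg <- c(msg, "outlierRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Latent-factor loading implied by a target inter-regional correlation
#'
#' In the single-factor generative model each region value contains a shared
#' term `b * f_i` plus independent noise with SD `sigma`, so any two regions
#' correlate at \eqn{r = b^2 / (b^2 + \sigma^2)}. This inverts that relation.
#'
#' @param r target pairwise correlation in `[0, 1)`.
#' @param noiseSd residual SD sigma (default 1).
#' @return loading `b = sigma * sqrt(r / (1 - r))`.
#' @examples
#' b <- loadingForCorrelation(0.30)
#' b^2 / (b^2 + 1)   # 0.30
#' @export
loadingForCorrelation <- function(r, noiseSd = 1) {
    assertThat(all(r >= 0 & r < 1), "target correlation must be in [0, 1)")
    noiseSd * sqrt(r / (1 - r))
}

#' @rdname SimulationConfig-class
#'
#' @details
#' The defaults describe the cohort the pipeline is designed for: 16,670
#' non-carriers and 120 carriers of schizophrenia-associated CNVs (49% of
#' them 15q11.2 deletions), with 320 participants removed by diagnosis
#' codes, 980 by array sample QC and 444 as carriers of other pathogenic
#' CNVs, so that the participant funnel is
#' 18,534 -> 18,214 -> 17,234 -> 16,790. Default carrier mean shifts are
#' -0.020 SD (surface area) and +0.015 SD (thickness); default factor
#' loadings imply inter-regional correlations tanh(0.31) vs tanh(0.22)
#' for thickness and tanh(0.16) vs tanh(0.14) for surface area
#' (carriers vs non-carriers).
#'
#' @param nNoncarriers,nCarriersPerLocus,nExcludedByCodes,nFailSampleQc,nPathogenic,nRegions,measures,meanShift,factorLoading,noiseSd,covariateEffects,outlierRate,callFailProbes,callFailDensity,seed see slot documentation.
#' @return a validated `SimulationConfig`.
#' @export
simulationConfig <- function(nNoncarriers = 16670L,
                             nCarriersPerLocus = c("15q11.2del" = 59L,
                                                   "16p13.11dup" = 18L,
                                                   "1q21.1dup" = 14L,
                                                   "1q21.1del" = 11L,
                                                   "16p11.2dup" = 10L,
                                                   "2p16.3del" = 8L),
                             nExcludedByCodes = 320L,
                             nFailSampleQc = 980L,
                             nPathogenic = 444L,
                             nRegions = 68L,
                             measures = corticalMeasures(),
                             meanShift = NULL,
                             factorLoading = NULL,
                             noiseSd = 1,
                             covariateEffects = NULL,
                             outlierRate = 0.001,
                             callFailProbes = 30L,
                             callFailDensity = 20L,
                             seed = 1L) {
    loci <- names(nCarriersPerLocus)
    if (is.null(meanShift)) {
        meanShift <- list(
            thickness = stats::setNames(rep(0.015, length(loci)), loci),
            surface_area = stats::setNames(rep(-0.020, length(loci)), loci))
    }
    if (is.null(factorLoading)) {
        factorLoading <- list(
            thickness = c(carrier = loadingForCorrelation(tanh(0.31), noiseSd),
                          non_carrier = loadingForCorrelation(tanh(0.22), noiseSd)),
            surface_area = c(carrier = loadingForCorrelation(tanh(0.16), noiseSd),
                             non_carrier = loadingForCorrelation(tanh(0.14), noiseSd)))
    }
    if (is.null(covariateEffects)) {
        covariateEffects <- list(
            thickness = c(age = -0.10, sex = -0.02, icv = 0.05, centre = 0.02),
            surface_area = c(age = -0.10, sex = 0.10, icv = 0.15, centre = 0.02))
    }
    storage.mode(nCarriersPerLocus) <- "integer"
    new("SimulationConfig",
        nNoncarriers = as.integer(nNoncarriers),
        nCarriersPerLocus = nCarriersPerLocus,
        nExcludedByCodes = as.integer(nExcludedByCodes),
        nFailSampleQc = as.integer(nFailSampleQc),
        nPathogenic = as.integer(nPathogenic),
        nRegions = as.integer(nRegions),
        measures = measures,
        meanShift = meanShift[measures],
        factorLoading = factorLoading[measures],
        noiseSd = noiseSd,
        covariateEffects = covariateEffects[measures],
        outlierRate = outlierRate,
        callFailProbes = as.integer(callFailProbes),
        callFailDensity = as.integer(callFailDensity),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  non-carriers:", object@nNoncarriers, "\n")
    cat("  carriers:    ", sum(object@nCarriersPerLocus), "across",
        length(object@nCarriersPerLocus), "loci\n")
    cat("  excluded:    ", object@nExcludedByCodes, "codes /",
        object@nFailSampleQc, "sample QC /", object@nPathogenic,
        "pathogenic\n")
    cat("  regions:     ", object@nRegions, " measures:",
        paste(object@measures, collapse = ", "), "\n")
    cat("  seed:        ", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# SyntheticCohort
# ---------------------------------------------------------------------------

#' SyntheticCohort: generated cohort plus generating truth
#'
#' @slot cohort a [CorticalCohort-class] with all configured assays, all
#'   participants (including those destined for exclusion) and covariates.
#' @slot truth list recording the generating parameters (per-measure delta
#'   and loadings, seed) and per-participant truth labels.
#' @export
setClass("SyntheticCohort",
    representation(cohort = "CorticalCohort", truth = "list"))

#' @describeIn SyntheticCohort-class the generated [CorticalCohort-class].
#' @param x a SyntheticCohort.
#' @export
cohortData <- function(x) x@cohort

#' @describeIn SyntheticCohort-class the truth record (generating
#'   parameters and per-participant labels).
#' @export
cohortTruth <- function(x) x@truth

setMethod("show", "SyntheticCohort", function(object) {
    g <- table(cohortGroups(object@cohort))
    cat("SyntheticCohort:", ncol(object@cohort), "participants x",
        nrow(object@cohort), "regions;",
        paste(assayNames(object@cohort), collapse = "+"), "\n")
    cat("  groups:", paste(names(g), g, sep = "=", collapse = ", "), "\n")
    cat("  seed:", object@truth$seed, "\n")
})

# ---------------------------------------------------------------------------
# CovarianceSummary
# ---------------------------------------------------------------------------

#' CovarianceSummary: Fisher-z structural covariance of one group
#'
#' Holds the gyrus x gyrus matrix of Fisher z-transformed Pearson
#' correlations for one group and one measure, the per-gyrus integration
#' index (mean z with all other gyri) and the overall covariance (mean of
#' the integration indices).
#'
#' @slot measure measure name.
#' @slot group group label.
#' @slot n number of participants the correlations were computed over.
#' @slot zmat symmetric numeric matrix of Fisher z values, diagonal NA.
#' @slot integration named numeric vector of per-gyrus integration indices.
#' @slot overall single numeric, the overall covariance.
#' @export
setClass("CovarianceSummary",
    representation(measure = "character", group = "character", n = "integer",
                   zmat = "matrix", integration = "numeric",
                   overall = "numeric"))

#' @describeIn CovarianceSummary-class the Fisher-z matrix.
#' @param x a CovarianceSummary.
#' @export
zMat <- function(x) x@zmat

#' Per-gyrus integration index
#'
#' The integration index of a gyrus is the mean of its Fisher-z
#' correlations with all other gyri (the off-diagonal row mean of the
#' z-matrix, missing cells skipped). For a [CovarianceSummary-class] the
#' stored indices are returned; for a raw z-matrix they are computed.
#'
#' @param x a CovarianceSummary or a symmetric z-matrix.
#' @param ... unused.
#' @return named numeric vector, one entry per gyrus.
#' @export
setGeneric("integrationIndex", function(x, ...) standardGeneric("integrationIndex"))

#' @rdname integrationIndex
#' @export
setMethod("integrationIndex", "CovarianceSummary", function(x, ...) x@integration)

#' @describeIn CovarianceSummary-class the overall covariance scalar.
#' @export
overallValue <- function(x) x@overall

setMethod("show", "CovarianceSummary", function(object) {
    cat(sprintf(
        "CovarianceSummary: %s, group '%s' (n=%d)\n  overall z = %.4f; %d gyri\n",
        object@measure, object@group, object@n, object@overall,
        length(object@integration)))
})

# ---------------------------------------------------------------------------
# NullDistribution
# ---------------------------------------------------------------------------

#' NullDistribution: resampled null statistics for group comparison
#'
#' Stores `B` replicates of a covariance statistic, each computed on a
#' random subset of non-carriers of the same size as the carrier group.
#' `values` is a `B x d` matrix where `d` is the dimension of the statistic
#' (1 for `overall`, one column per gyrus for `integration`, per component
#' for `component`, per gyrus pair for `cell`).
#'
#' @slot statistic one of "overall", "integration", "component", "cell".
#' @slot B replicate count.
#' @slot values B x d numeric matrix of null statistics.
#' @slot seed the RNG seed the replicates were drawn under.
#' @export
setClass("NullDistribution",
    representation(statistic = "character", B = "integer",
                   values = "matrix", seed = "integer"))

setValidity("NullDistribution", function(object) {
    if (nrow(object@values) != object@B)
        "nrow(values) must equal B" else TRUE
})

#' @describeIn NullDistribution-class the B x d matrix of null statistics.
#' @param x a NullDistribution.
#' @export
nullValues <- function(x) x@values

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf("NullDistribution: '%s', B = %d, dim = %d (seed %d)\n",
                object@statistic, object@B, ncol(object@values),
                object@seed))
})
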