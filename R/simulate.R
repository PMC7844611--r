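#' @importFrom stats rnorm runif rbinom rpois setNames sd
NULL

# Deterministic participant frame: ids, truth group, carrier locus and the
# sample-QC failure mode for the participants destined to fail it. Shared by
# simulateCohort() and simulateCnvFixtures() so both operate on the same
# cohort.
.sampleFrame <- function(config) {
    nc <- config@nCarriersPerLocus
    groups <- c(rep("carrier", sum(nc)),
                rep("non_carrier", config@nNoncarriers),
                rep("excluded_pathogenic", config@nPathogenic),
                rep("excluded_qc", config@nFailSampleQc),
                rep("excluded_code", config@nExcludedByCodes))
    locus <- c(rep(names(nc), nc), rep(NA_character_, length(groups) - sum(nc)))
    n <- length(groups)
    qc_mode <- rep(NA_character_, n)
    iqc <- which(groups == "excluded_qc")
    if (length(iqc))
        qc_mode[iqc] <- rep(c("n_cnvs", "waviness_pos", "waviness_neg",
                              "call_rate"), length.out = length(iqc))
    data.frame(participant_id = sprintf("S%06d", seq_len(n)),
               group = groups, locus = locus, qc_mode = qc_mode,
               stringsAsFactors = FALSE)
}

# CNV-stage truth status (diagnosis codes are a later, independent stage)
.cnvTruthStatus <- function(group) {
    ifelse(group == "excluded_qc", "excluded_qc",
    ifelse(group == "carrier", "carrier",
    ifelse(group == "excluded_pathogenic", "excluded_pathogenic",
           "non_carrier")))
}

.regionNames <- function(nRegions) {
    if (nRegions == 68L) dkRegions() else sprintf("region%02d", seq_len(nRegions))
}

# region-level baseline means and the measure-level scale used to map the
# standardized generative scale onto mm / mm^2
.regionMeans <- function(measure, nRegions) {
    switch(measure,
           thickness = seq(2.0, 3.0, length.out = nRegions),
           surface_area = seq(1000, 4000, length.out = nRegions))
}

.measureScale <- function(measure) {
    switch(measure, thickness = 0.12, surface_area = 330)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a latent single-factor model. On a standardized
#' scale, the value of region \eqn{g} for participant \eqn{i} is
#' \deqn{z_{ig} = \delta \cdot carrier_i + X_i \beta + b_{grp(i)} f_i +
#'   \epsilon_{ig}}
#' with \eqn{f_i} standard normal (one independent factor per measure),
#' \eqn{\epsilon_{ig}} normal with SD `noiseSd`, covariate effects
#' \eqn{\beta} applied to standardized age/ICV and to the binary sex and
#' centre indicators, carrier mean shift \eqn{\delta} per locus, and
#' factor loading \eqn{b} depending on carrier status. The shared factor
#' makes any two regions within a group correlate at
#' \eqn{r = b^2/(b^2 + noiseSd^2)} (see [loadingForCorrelation()]); when
#' covariate effects are non-zero their shared signal adds a small further
#' common term. Values are then mapped to measurement units via fixed
#' region means and a per-measure scale. Covariates are drawn as age
#' uniform on 45-80 years, sex Bernoulli(0.53) (1 = female), ICV normal
#' (mean 1.55e6 mm^3, SD 1.5e5) and centre Bernoulli(0.157) reflecting the
#' two-centre imbalance. A fraction `outlierRate` of assay values is
#' replaced by the column mean +/- 6 column SDs to emulate segmentation
#' failures.
#'
#' Everything is deterministic given `config@seed`.
#'
#' @param config a [simulationConfig()].
#' @return a [SyntheticCohort-class].
#' @examples
#' sc <- simulateCohort(simulationConfig(
#'     nNoncarriers = 50, nCarriersPerLocus = c(locusA = 10),
#'     nExcludedByCodes = 0, nFailSampleQc = 0, nPathogenic = 0,
#'     nRegions = 8, outlierRate = 0, seed = 7))
#' cohortData(sc)
#' @export
simulateCohort <- function(config) {
    validObject(config)
    frame <- .sampleFrame(config)
    n <- nrow(frame)
    G <- config@nRegions
    regions <- .regionNames(G)
    is_carrier <- frame$group == "carrier"

    withSeed(config@seed, {
        age <- runif(n, 45, 80)
        sex <- rbinom(n, 1, 0.53)
        icv <- rnorm(n, 1.55e6, 1.5e5)
        centre <- rbinom(n, 1, 0.157)
        age_z <- (age - 62.5) / (35 / sqrt(12))
        icv_z <- (icv - 1.55e6) / 1.5e5

        assays <- list()
        outlier_truth <- list()
        for (m in config@measures) {
            delta <- rep(0, n)
            dm <- config@meanShift[[m]]
            hit <- is_carrier & frame$locus %in% names(dm)
            delta[hit] <- dm[frame$locus[hit]]
            b <- ifelse(is_carrier, config@factorLoading[[m]]["carrier"],
                        config@factorLoading[[m]]["non_carrier"])
            beta <- config@covariateEffects[[m]]
            fixed <- delta + beta["age"] * age_z + beta["sex"] * sex +
                beta["icv"] * icv_z + beta["centre"] * centre
            f <- rnorm(n)
            z <- matrix(rnorm(n * G, sd = config@noiseSd), n, G)
            z <- z + fixed + b * f
            vals <- .measureScale(m) * t(z) + .regionMeans(m, G)
            dimnames(vals) <- list(regions, frame$participant_id)
            out_idx <- integer(0)
            if (config@outlierRate > 0) {
                out_idx <- which(runif(n * G) < config@outlierRate)
                if (length(out_idx)) {
                    rr <- ((out_idx - 1L) %% G) + 1L
                    mu <- rowMeans(vals)[rr]
                    sdv <- apply(vals, 1, sd)[rr]
                    sign6 <- sample(c(-1, 1), length(out_idx), replace = TRUE)
                    vals[out_idx] <- mu + sign6 * 6 * sdv
                }
            }
            assays[[m]] <- vals
            outlier_truth[[m]] <- out_idx
        }

        codes <- .assignCodes(frame, n)
        covariates <- data.frame(
            participant_id = frame$participant_id,
            group = frame$group, locus = frame$locus,
            age = age, sex = sex, icv = icv, centre = centre,
            self_report_codes = codes$self_report,
            icd10_codes = codes$icd10,
            stringsAsFactors = FALSE)

        cohort <- corticalCohort(assays, covariates)
        truth <- list(delta = config@meanShift,
                      loading = config@factorLoading,
                      noiseSd = config@noiseSd,
                      seed = config@seed,
                      labels = frame,
                      outliers = outlier_truth)
        new("SyntheticCohort", cohort = cohort, truth = truth)
    })
}

# diagnosis codes: excluded_code participants cycle through excluding codes
# (mixing self-report and ICD-10, including an F11-F19 range hit); ~25% of
# the others get a benign code.
.assignCodes <- function(frame, n) {
    excluding <- list(
        list(sr = "1289", icd = ""), list(sr = "", icd = "F25.1"),
        list(sr = "1291", icd = ""), list(sr = "", icd = "F12.5"),
        list(sr = "1408", icd = ""), list(sr = "", icd = "G35"),
        list(sr = "1263", icd = ""), list(sr = "", icd = "F84.0"))
    sr <- rep("", n); icd <- rep("", n)
    benign <- runif(n) < 0.25
    sr[benign] <- sample(c("1473", "1065"), sum(benign), replace = TRUE)
    icd[benign] <- ifelse(runif(sum(benign)) < 0.5, "I10", "J45.9")
    iex <- which(frame$group == "excluded_code")
    for (k in seq_along(iex)) {
        e <- excluding[[((k - 1L) %% length(excluding)) + 1L]]
        sr[iex[k]] <- e$sr
        icd[iex[k]] <- e$icd
    }
    list(self_report = sr, icd10 = icd)
}

#' Generate synthetic CNV calls and sample-QC fixtures
#'
#' Emits PennCNV-style CNV calls and a sample-QC table for the cohort
#' described by `config`, with ground-truth labels attached: carriers of
#' each configured SCZ locus receive a call matching that locus under
#' [matchLocus()]; `nPathogenic` participants receive a call matching a
#' `pathogenic_other` locus; `nFailSampleQc` participants fail sample QC
#' (cycling through the >30 CNVs, waviness and call-rate rules); and
#' `callFailProbes` / `callFailDensity` additional calls fail the
#' call-level filters. All other calls are benign: they pass the filters
#' but are placed on chromosomes carrying no locus. Deterministic given
#' `config@seed`.
#'
#' @param config a [simulationConfig()].
#' @param loci locus definitions (see [locusDefinition()]); must contain a
#'   `scz_associated` entry for every name in `config@nCarriersPerLocus`,
#'   and at least one `pathogenic_other` locus when `nPathogenic > 0`.
#' @return list with elements `calls` (a `GRanges` with mcols `sample_id`,
#'   `state`, `n_probes`, `truth`) and `sampleQc` (data.frame with
#'   `sample_id`, `n_cnvs`, `waviness`, `call_rate`, `truth_status`).
#' @export
simulateCnvFixtures <- function(config, loci) {
    validObject(config)
    assertThat(length(loci) > 0, "'loci' must be non-empty")
    lmc <- mcols(loci)
    need <- names(config@nCarriersPerLocus)
    missing_loci <- setdiff(need, lmc$locus[lmc$category == "scz_associated"])
    assertThat(length(missing_loci) == 0,
               "no scz_associated definition for locus/loci: %s",
               paste(missing_loci, collapse = ", "))
    path_loci <- loci[lmc$category == "pathogenic_other"]
    assertThat(config@nPathogenic == 0L || length(path_loci) > 0,
               "nPathogenic > 0 but no pathogenic_other locus supplied")

    frame <- .sampleFrame(config)
    n <- nrow(frame)
    benign_chroms <- setdiff(paste0("chr", 1:22),
                             as.character(unique(seqnames(loci))))
    assertThat(length(benign_chroms) > 0,
               "loci occupy all chromosomes; no room for benign calls")

    withSeed(config@seed + 1L, {
        ## benign background calls: 0-3 per participant, always pass filters
        nben <- sample(0:3, n, replace = TRUE)
        who <- rep(frame$participant_id, nben)
        tot <- length(who)
        bchr <- sample(benign_chroms, tot, replace = TRUE)
        bw <- round(runif(tot, 2e4, 2e5))
        bs <- round(runif(tot, 1e6, 1.2e8))
        bnp <- pmax(10L, as.integer(round(bw / 10000)))
        calls <- data.frame(chrom = bchr, start = bs, end = bs + bw - 1,
                            state = sample(c("del", "dup"), tot, TRUE),
                            n_probes = bnp, sample_id = who,
                            truth = "benign", stringsAsFactors = FALSE)

        ## locus-matching calls for carriers and pathogenic carriers
        mk_match <- function(sample_id, locus_gr) {
            md <- mcols(locus_gr)
            chrom <- as.character(seqnames(locus_gr))
            if (isTRUE(md$single_gene)) {
                if (md$dosage == "del") {
                    ex <- md$exons[[1]][1]   # clip first exon only
                    s <- start(ex) - round(runif(1, 5e3, 5e4))
                    e <- start(ex) + round(width(ex) / 2)
                } else {
                    gs <- md$gene_span[[1]]
                    s <- start(gs) - round(runif(1, 1e3, 2e4))
                    e <- end(gs) + round(runif(1, 1e3, 2e4))
                }
            } else {
                s <- start(locus_gr) - round(runif(1, 1e3, 5e4))
                e <- end(locus_gr) + round(runif(1, 1e3, 5e4))
            }
            w <- e - s + 1
            data.frame(chrom = chrom, start = s, end = e, state = md$dosage,
                       n_probes = max(10L, as.integer(ceiling(w / 15000))),
                       sample_id = sample_id, truth = NA_character_,
                       stringsAsFactors = FALSE)
        }
        carr <- frame[frame$group == "carrier", ]
        for (k in seq_len(nrow(carr))) {
            lg <- loci[lmc$locus == carr$locus[k] &
                       lmc$category == "scz_associated"]
            row <- mk_match(carr$participant_id[k], lg[1])
            row$truth <- "carrier_match"
            calls <- rbind(calls, row)
        }
        path <- frame[frame$group == "excluded_pathogenic", ]
        for (k in seq_len(nrow(path))) {
            lg <- path_loci[((k - 1L) %% length(path_loci)) + 1L]
            row <- mk_match(path$participant_id[k], lg)
            row$truth <- "pathogenic_match"
            calls <- rbind(calls, row)
        }

        ## call-level filter failures attached to random non-carriers
        eligible <- frame$participant_id[frame$group == "non_carrier"]
        mk_fail <- function(k, mode) {
            sid <- sample(eligible, k, replace = TRUE)
            chrom <- sample(benign_chroms, k, replace = TRUE)
            if (mode == "probes") {
                w <- round(runif(k, 2e4, 1e5))
                np <- sample(1:9, k, replace = TRUE)
            } else {
                w <- round(runif(k, 2.5e5, 4e5))
                np <- rep(10L, k)          # 10 probes over >200 kb: too sparse
            }
            s <- round(runif(k, 1e6, 1.2e8))
            data.frame(chrom = chrom, start = s, end = s + w - 1,
                       state = sample(c("del", "dup"), k, TRUE),
                       n_probes = as.integer(np), sample_id = sid,
                       truth = paste0("fail_", mode),
                       stringsAsFactors = FALSE)
        }
        if (config@callFailProbes > 0)
            calls <- rbind(calls, mk_fail(config@callFailProbes, "probes"))
        if (config@callFailDensity > 0)
            calls <- rbind(calls, mk_fail(config@callFailDensity, "density"))

        ## sample-QC metrics
        ncalls <- table(factor(calls$sample_id, levels = frame$participant_id))
        qc <- data.frame(sample_id = frame$participant_id,
                         n_cnvs = as.integer(ncalls),
                         waviness = runif(n, -0.02, 0.02),
                         call_rate = runif(n, 0.965, 0.995),
                         truth_status = .cnvTruthStatus(frame$group),
                         stringsAsFactors = FALSE)
        iqc <- which(frame$group == "excluded_qc")
        qc$n_cnvs[iqc][frame$qc_mode[iqc] == "n_cnvs"] <- 31L
        qc$waviness[iqc][frame$qc_mode[iqc] == "waviness_pos"] <- 0.05
        qc$waviness[iqc][frame$qc_mode[iqc] == "waviness_neg"] <- -0.05
        qc$call_rate[iqc][frame$qc_mode[iqc] == "call_rate"] <- 0.95

        gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end))
        mcols(gr) <- S4Vectors::DataFrame(sample_id = calls$sample_id,
                                          state = calls$state,
                                          n_probes = calls$n_probes,
                                          truth = calls$truth)
        list(calls = gr, sampleQc = qc)
    })
}

# ---------------------------------------------------------------------------
# plain-text writers / readers for the pipeline file interface
# ---------------------------------------------------------------------------

#' Write / read the cohort file interface
#'
#' `writeCohortFiles()` writes one CSV per measure
#' (`cohort_<measure>.csv`: participant_id, group, then one column per
#' region), a covariate CSV, a PennCNV-like calls TSV (chrom, start, end,
#' state, num_snp, sample_id) and a sample-QC TSV.
#' `readCohortCsv()`/`readCnvCalls()`/`readSampleQc()` read them back.
#'
#' @param sc a [SyntheticCohort-class].
#' @param fixtures output of [simulateCnvFixtures()] (optional).
#' @param dir output directory, created if needed.
#' @return `writeCohortFiles()`: invisibly, the paths written.
#' @export
writeCohortFiles <- function(sc, dir, fixtures = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cc <- cohortData(sc)
    paths <- character(0)
    for (m in assayNames(cc)) {
        df <- data.frame(participant_id = colnames(cc),
                         group = cohortGroups(cc),
                         t(assay(cc, m)), check.names = FALSE)
        p <- file.path(dir, paste0("cohort_", m, ".csv"))
        utils::write.csv(df, p, row.names = FALSE)
        paths <- c(paths, p)
    }
    cov_cols <- c("participant_id", "group", "locus", "age", "sex", "icv",
                  "centre", "self_report_codes", "icd10_codes")
    cov <- as.data.frame(colData(cc))[, cov_cols]
    p <- file.path(dir, "covariates.csv")
    utils::write.csv(cov, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(fixtures)) {
        calls <- fixtures$calls
        df <- data.frame(chrom = as.character(seqnames(calls)),
                         start = start(calls), end = end(calls),
                         state = mcols(calls)$state,
                         num_snp = mcols(calls)$n_probes,
                         sample_id = mcols(calls)$sample_id)
        p <- file.path(dir, "cnv_calls.tsv")
        utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
        p <- file.path(dir, "sample_qc.tsv")
        utils::write.table(fixtures$sampleQc[, c("sample_id", "n_cnvs",
                                                 "waviness", "call_rate")],
                           p, sep = "\t", row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' @rdname writeCohortFiles
#' @param paths named character vector of `cohort_<measure>.csv` paths
#'   (names = measures).
#' @param covariatePath path to the covariate CSV.
#' @export
readCohortCsv <- function(paths, covariatePath) {
    assays <- list()
    for (m in names(paths)) {
        df <- utils::read.csv(paths[[m]], check.names = FALSE)
        mat <- t(as.matrix(df[, setdiff(names(df), c("participant_id", "group")),
                              drop = FALSE]))
        colnames(mat) <- df$participant_id
        assays[[m]] <- mat
    }
    cov <- utils::read.csv(covariatePath, colClasses = list(
        self_report_codes = "character", icd10_codes = "character"))
    corticalCohort(assays, cov)
}

#' @rdname writeCohortFiles
#' @param path a TSV path.
#' @export
readCnvCalls <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "state", "num_snp", "sample_id")
    assertThat(all(need %in% names(df)),
               "calls TSV must have columns: %s", paste(need, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr) <- S4Vectors::DataFrame(sample_id = df$sample_id,
                                      state = df$state,
                                      n_probes = as.integer(df$num_snp))
    gr
}

#' @rdname writeCohortFiles
#' @export
readSampleQc <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "n_cnvs", "waviness", "call_rate")
    assertThat(all(need %in% names(df)),
               "sample QC TSV must have columns: %s",
               paste(need, collapse = ", "))
    df
}
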