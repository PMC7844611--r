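#' Exclusion code lists
#'
#' `exclusionCodeList()` bundles the self-reported diagnosis codes and the
#' ICD-10 codes (single codes, prefixes, or ranges such as `"F11-F19"`)
#' that exclude a participant. `defaultExclusionCodes()` returns the
#' severe neuropsychiatric / neurological exclusion set used for
#' carrier-status analyses (psychotic and bipolar disorders, substance
#' dependence, dementia and neurodegenerative disease, developmental
#' disorders).
#'
#' @param selfReport character or integer vector of self-report codes.
#' @param icd10 character vector of ICD-10 codes; an entry may be a code
#'   (`"F25"`, matched as a prefix after dot removal, so it catches
#'   `"F25.1"`) or a range (`"F11-F19"`, matched on the letter + two-digit
#'   category).
#' @return a list with elements `self_report` and `icd10`.
#' @export
exclusionCodeList <- function(selfReport, icd10) {
    assertThat(length(selfReport) + length(icd10) > 0,
               "exclusion code list must be non-empty")
    icd10 <- toupper(gsub("\\.", "", icd10))
    for (e in icd10[grepl("-", icd10)]) {
        ok <- grepl("^[A-Z][0-9]+-[A-Z][0-9]+$", e) &&
            substr(e, 1, 1) == sub("^.*-([A-Z]).*$", "\\1", e)
        if (ok) {
            parts <- strsplit(e, "-")[[1]]
            ok <- as.integer(sub("^[A-Z]", "", parts[1])) <=
                as.integer(sub("^[A-Z]", "", parts[2]))
        }
        assertThat(ok, "malformed ICD-10 range: '%s'", e)
    }
    list(self_report = as.character(selfReport), icd10 = icd10)
}

#' @rdname exclusionCodeList
#' @export
defaultExclusionCodes <- function() {
    exclusionCodeList(
        selfReport = c(1410, 1409, 1408, 1291, 1289, 1263, 1262, 1261,
                       1259, 1258),
        icd10 = c("Q90", "F84", "F71", "F72", "F73", "F78", "F79", "F81",
                  "F30", "F31", "F21", "F22", "F23", "F28", "F29", "F25",
                  "F11-F19", "F10", "F00", "F01", "F02", "F03", "F04",
                  "G30", "R54", "G35-G37", "G11", "G13", "G23", "G31",
                  "G32", "G20-G22", "G122", "G10"))
}

# does one normalized ICD-10 code (dots stripped) hit the list?
.icdHit <- function(code, icd_list) {
    if (code == "") return(FALSE)
    letter <- substr(code, 1, 1)
    catnum <- suppressWarnings(as.integer(substr(code, 2, 3)))
    for (e in icd_list) {
        if (grepl("-", e)) {
            parts <- strsplit(e, "-")[[1]]
            if (letter == substr(parts[1], 1, 1) && !is.na(catnum) &&
                catnum >= as.integer(sub("^[A-Z]", "", parts[1])) &&
                catnum <= as.integer(sub("^[A-Z]", "", parts[2])))
                return(TRUE)
        } else if (startsWith(code, e)) {
            return(TRUE)
        }
    }
    FALSE
}

#' Exclude participants by diagnosis code
#'
#' A participant is excluded when any of their self-reported diagnosis
#' codes appears in the list, or any of their ICD-10 codes matches a
#' listed code (prefix match after dot removal) or falls inside a listed
#' category range such as `"F11-F19"`.
#'
#' @param participants data.frame with a `participant_id` column and
#'   columns `self_report_codes` and `icd10_codes` holding
#'   comma-separated code strings (empty string = none).
#' @param codes an [exclusionCodeList()].
#' @return the input with a logical column `excluded_code`.
#' @examples
#' p <- data.frame(participant_id = c("a", "b", "c"),
#'                 self_report_codes = c("1289", "", ""),
#'                 icd10_codes = c("", "F25.1", "I10"))
#' excludeByCodes(p, defaultExclusionCodes())$excluded_code
#' @export
excludeByCodes <- function(participants, codes = defaultExclusionCodes()) {
    need <- c("participant_id", "self_report_codes", "icd10_codes")
    assertThat(all(need %in% names(participants)),
               "participants must have columns: %s",
               paste(need, collapse = ", "))
    sr <- splitCodes(participants$self_report_codes)
    icd <- splitCodes(participants$icd10_codes)
    hit_sr <- vapply(sr, function(v) any(v %in% codes$self_report), logical(1))
    hit_icd <- vapply(icd, function(v) {
        v <- toupper(gsub("\\.", "", v))
        any(vapply(v, .icdHit, logical(1), icd_list = codes$icd10))
    }, logical(1))
    participants$excluded_code <- hit_sr | hit_icd
    participants
}

#' Remove extreme regional values
#'
#' For each region, values further than `k` standard deviations from that
#' region's mean are set to missing. Mean and SD are computed once over
#' all non-missing values of the region (single pass over the whole
#' analysis sample, not iterated), and the fence is strict: a value at
#' exactly `mean + k * SD` is kept. A region with zero SD loses nothing.
#'
#' Applying the rule twice would re-fence on the post-removal moments and
#' remove more, so the operation records a flag in the cohort metadata and
#' refuses to run twice on the same assay.
#'
#' @param x a [CorticalCohort-class] or a numeric matrix
#'   (regions x participants).
#' @param k fence width in SDs (default 2.5).
#' @param measures which assays to process (default: all).
#' @return object of the same class with extreme values set to `NA`.
#' @export
removeOutliers <- function(x, k = 2.5, measures = NULL) {
    if (is.matrix(x)) return(.fenceMatrix(x, k))
    assertThat(is(x, "CorticalCohort"),
               "x must be a CorticalCohort or a matrix")
    if (is.null(measures)) measures <- assayNames(x)
    done <- metadata(x)$outliers_removed
    for (m in measures) {
        assertThat(!isTRUE(done[[m]]),
                   "outlier removal already applied to assay '%s'", m)
        SummarizedExperiment::assay(x, m) <- .fenceMatrix(assay(x, m), k)
        done[[m]] <- TRUE
    }
    metadata(x)$outliers_removed <- done
    x
}

.fenceMatrix <- function(mat, k) {
    nn <- rowSums(!is.na(mat))
    assertThat(all(nn >= 3),
               "each region needs at least 3 non-missing values")
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, sd, na.rm = TRUE)
    lim <- k * sdv
    dev <- abs(mat - mu)
    mat[!is.na(mat) & sdv > 0 & dev > lim] <- NA
    mat
}

#' Assemble the analysis-ready dataset
#'
#' Inner-joins a cohort with a carrier-status table, restricts to
#' participants classified `carrier` or `non_carrier`, and (optionally)
#' drops participants flagged by [excludeByCodes()]. The participant's
#' analysis `group` is set from the status table; any pre-existing
#' `group` column (e.g. simulation truth labels) is preserved as
#' `truth_group`. Per-group sizes are recorded in the cohort metadata.
#'
#' @param cohort a [CorticalCohort-class].
#' @param statuses output of [classifyParticipants()].
#' @param codeExcluded optional character vector of participant ids to
#'   drop (diagnosis-code exclusions).
#' @return the restricted [CorticalCohort-class]; `metadata(x)$group_n`
#'   holds the per-group counts.
#' @export
assembleDataset <- function(cohort, statuses, codeExcluded = NULL) {
    assertThat(!anyDuplicated(statuses$sample_id),
               "duplicated participant id in status table")
    keep_ids <- statuses$sample_id[statuses$status %in%
                                   c("carrier", "non_carrier")]
    keep_ids <- setdiff(keep_ids, codeExcluded)
    keep_ids <- intersect(colnames(cohort), keep_ids)
    st <- setNames(statuses$status, statuses$sample_id)[keep_ids]
    assertThat(any(st == "carrier"), "empty carrier group after assembly")
    out <- cohort[, keep_ids]
    cd <- colData(out)
    if ("group" %in% colnames(cd)) cd$truth_group <- cd$group
    cd$group <- unname(st)
    ml <- setNames(statuses$matched_loci, statuses$sample_id)[keep_ids]
    cd$matched_loci <- unname(ml)
    colData(out) <- cd
    metadata(out)$group_n <- as.list(table(cd$group))
    out
}
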