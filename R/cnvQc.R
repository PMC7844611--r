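#' Sample-level CNV quality control
#'
#' A sample is excluded when it has more than 30 CNV calls, an absolute
#' waviness factor above 0.03, or a call rate below 96%. All comparisons
#' are strict, so a sample sitting exactly on a threshold (30 CNVs,
#' waviness 0.03, call rate 0.96) is kept.
#'
#' @param records data.frame with columns `sample_id`, `n_cnvs`,
#'   `waviness`, `call_rate` (see [readSampleQc()]).
#' @param maxCnvs,maxWaviness,minCallRate thresholds; defaults are the
#'   standard PennCNV-workflow values above.
#' @return the input with a logical column `excluded_qc` and a character
#'   column `qc_reason` (`NA` for kept samples).
#' @examples
#' qc <- data.frame(sample_id = c("a", "b"), n_cnvs = c(31L, 30L),
#'                  waviness = 0, call_rate = 0.99)
#' filterSamples(qc)$excluded_qc
#' @export
filterSamples <- function(records, maxCnvs = 30, maxWaviness = 0.03,
                          minCallRate = 0.96) {
    need <- c("sample_id", "n_cnvs", "waviness", "call_rate")
    assertThat(all(need %in% names(records)),
               "records must have columns: %s", paste(need, collapse = ", "))
    dup <- records$sample_id[duplicated(records$sample_id)]
    assertThat(length(dup) == 0, "duplicate sample_id in QC records: %s",
               paste(unique(dup), collapse = ", "))
    assertThat(all(records$call_rate >= 0 & records$call_rate <= 1),
               "call_rate must lie in [0, 1]")
    assertThat(all(records$n_cnvs >= 0), "n_cnvs must be non-negative")
    reason <- rep(NA_character_, nrow(records))
    reason[records$call_rate < minCallRate] <- "call_rate"
    reason[abs(records$waviness) > maxWaviness] <- "waviness"
    reason[records$n_cnvs > maxCnvs] <- "n_cnvs"
    records$excluded_qc <- !is.na(reason)
    records$qc_reason <- reason
    records
}

#' Call-level CNV filters
#'
#' A call is excluded when it is covered by fewer than 10 probes or its
#' probe density is below 1 probe per 20,000 bp. Both comparisons are
#' strict: 10 probes over exactly 200,000 bp (density exactly 1/20,000)
#' survives. Interval lengths are 1-based inclusive
#' (`end - start + 1`).
#'
#' @param calls `GRanges` with mcols `sample_id`, `state`, `n_probes`
#'   (see [readCnvCalls()]).
#' @param minProbes,minDensity thresholds (defaults 10 and 1/20,000).
#' @return the input with a logical mcol `excluded` and a character mcol
#'   `filter_reason`.
#' @export
filterCalls <- function(calls, minProbes = 10, minDensity = 1 / 20000) {
    np <- mcols(calls)$n_probes
    assertThat(!is.null(np), "calls must carry an 'n_probes' mcol")
    assertThat(all(np >= 1), "n_probes must be >= 1")
    len <- width(calls)
    assertThat(all(len > 0), "zero-length CNV interval")
    ## n/len < 1/20000  <=>  n * 20000 < len, exact in integer-valued doubles
    reason <- rep(NA_character_, length(calls))
    reason[np / minDensity < len] <- "density"
    reason[np < minProbes] <- "probes"
    mcols(calls)$excluded <- !is.na(reason)
    mcols(calls)$filter_reason <- reason
    calls
}

# 1-based inclusive overlap length between a call and one interval
.overlapLen <- function(call, iv) {
    if (as.character(seqnames(call)) != as.character(seqnames(iv)))
        return(0)
    max(0, min(end(call), end(iv)) - max(start(call), start(iv)) + 1)
}

.contains <- function(call, iv) {
    as.character(seqnames(call)) == as.character(seqnames(iv)) &&
        start(call) <= start(iv) && end(call) >= end(iv)
}

#' Match a CNV call against a locus definition
#'
#' A call matches a multi-gene locus when its state equals the locus
#' dosage, it covers strictly more than half of the critical interval
#' (overlap measured against the critical interval, 1-based inclusive),
#' and it fully contains every key gene. For single-gene loci the rule is
#' dosage-specific: deletions match when they intersect at least one exon
#' by at least 1 bp; duplications only when they contain the whole gene
#' span. A chromosome mismatch is simply a non-match.
#'
#' @param call `GRanges` of length 1 with mcols `state`, `n_probes`.
#' @param locus a locus definition (see [locusDefinition()]).
#' @return logical.
#' @examples
#' loc <- locusDefinition("L", "chr1", 1000, 1999, "del")
#' call <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1501))
#' S4Vectors::mcols(call)$state <- "del"
#' matchLocus(call, loc)   # covers 502/1000 bp > half
#' @export
matchLocus <- function(call, locus) {
    assertThat(length(call) == 1L && length(locus) == 1L,
               "matchLocus() compares one call against one locus")
    md <- mcols(locus)
    if (mcols(call)$state != md$dosage) return(FALSE)
    if (as.character(seqnames(call)) != as.character(seqnames(locus)))
        return(FALSE)
    if (isTRUE(md$single_gene)) {
        if (md$dosage == "del") {
            ex <- md$exons[[1]]
            return(any(vapply(seq_along(ex),
                              function(i) .overlapLen(call, ex[i]) >= 1,
                              logical(1))))
        }
        return(.contains(call, md$gene_span[[1]]))
    }
    ov <- .overlapLen(call, locus)
    if (2 * ov <= width(locus)) return(FALSE)     # strictly more than half
    kg <- md$key_genes[[1]]
    all(vapply(seq_along(kg), function(i) .contains(call, kg[i]), logical(1)))
}

#' Classify participants by CNV carrier status
#'
#' Applies [filterSamples()] and [filterCalls()], matches every surviving
#' call against the locus definitions with [matchLocus()], and assigns
#' each sample exactly one status:
#' \describe{
#'   \item{excluded_qc}{the sample failed sample-level QC;}
#'   \item{carrier}{at least one surviving call matches a
#'     schizophrenia-associated locus (`matched_loci` lists them all);}
#'   \item{excluded_pathogenic}{no SCZ match, but at least one call matches
#'     another pathogenic locus;}
#'   \item{non_carrier}{none of the above.}
#' }
#' A sample matching both an SCZ locus and another pathogenic locus is
#' classified `carrier` (SCZ takes precedence) and flagged in
#' `dual_carrier` for sensitivity analyses.
#'
#' @param calls `GRanges` of CNV calls (mcols `sample_id`, `state`,
#'   `n_probes`).
#' @param sampleQc sample-QC data.frame; every sample appearing in `calls`
#'   must be present (a call for an unknown sample is a hard error).
#' @param loci locus definitions containing both categories.
#' @param maxCnvs,maxWaviness,minCallRate,minProbes,minDensity QC
#'   thresholds, passed to [filterSamples()] and [filterCalls()].
#' @return data.frame with columns `sample_id`, `status`, `matched_loci`
#'   (comma-separated, `""` unless carrier) and `dual_carrier`.
#' @export
classifyParticipants <- function(calls, sampleQc, loci, maxCnvs = 30,
                                 maxWaviness = 0.03, minCallRate = 0.96,
                                 minProbes = 10, minDensity = 1 / 20000) {
    qc <- filterSamples(sampleQc, maxCnvs = maxCnvs,
                        maxWaviness = maxWaviness,
                        minCallRate = minCallRate)
    missing_ids <- setdiff(unique(mcols(calls)$sample_id), qc$sample_id)
    assertThat(length(missing_ids) == 0,
               "calls present for sample(s) absent from sample QC: %s",
               paste(utils::head(missing_ids, 5), collapse = ", "))

    fc <- filterCalls(calls, minProbes = minProbes, minDensity = minDensity)
    kept <- fc[!mcols(fc)$excluded]
    md <- mcols(loci)

    ## vectorized matching: evaluate each locus against all kept calls
    n_kept <- length(kept)
    scz_hit <- matrix(FALSE, n_kept, 0)
    scz_names <- character(0)
    path_hit <- rep(FALSE, n_kept)
    for (j in seq_along(loci)) {
        hits <- .matchLocusVec(kept, loci[j])
        if (md$category[j] == "scz_associated") {
            scz_hit <- cbind(scz_hit, hits)
            scz_names <- c(scz_names, md$locus[j])
        } else {
            path_hit <- path_hit | hits
        }
    }

    sid <- mcols(kept)$sample_id
    status <- setNames(rep("non_carrier", nrow(qc)), qc$sample_id)
    matched <- setNames(rep("", nrow(qc)), qc$sample_id)
    dual <- setNames(rep(FALSE, nrow(qc)), qc$sample_id)
    hit_rows <- which(rowSums(scz_hit) > 0 | path_hit)
    if (length(hit_rows)) {
        by_sample <- split(hit_rows, sid[hit_rows])
        for (s in names(by_sample)) {
            rows <- by_sample[[s]]
            loci_hit <- scz_names[colSums(scz_hit[rows, , drop = FALSE]) > 0]
            any_path <- any(path_hit[rows])
            if (length(loci_hit)) {
                status[s] <- "carrier"
                matched[s] <- paste(sort(unique(loci_hit)), collapse = ",")
                dual[s] <- any_path
            } else if (any_path) {
                status[s] <- "excluded_pathogenic"
            }
        }
    }
    status[qc$excluded_qc] <- "excluded_qc"   # sample QC overrides everything
    matched[qc$excluded_qc] <- ""
    dual[qc$excluded_qc] <- FALSE

    data.frame(sample_id = qc$sample_id, status = unname(status),
               matched_loci = unname(matched), dual_carrier = unname(dual),
               stringsAsFactors = FALSE)
}

# vectorized matchLocus over many calls, one locus
.matchLocusVec <- function(calls, locus) {
    if (!length(calls)) return(logical(0))
    md <- mcols(locus)
    out <- rep(FALSE, length(calls))
    cand <- mcols(calls)$state == md$dosage &
        as.character(seqnames(calls)) == as.character(seqnames(locus))
    if (!any(cand)) return(out)
    idx <- which(cand)
    cs <- start(calls)[idx]; ce <- end(calls)[idx]
    if (isTRUE(md$single_gene)) {
        if (md$dosage == "del") {
            ex <- md$exons[[1]]
            hit <- rep(FALSE, length(idx))
            for (i in seq_along(ex))
                hit <- hit | (pmin(ce, end(ex)[i]) - pmax(cs, start(ex)[i]) + 1 >= 1)
            out[idx] <- hit
        } else {
            gs <- md$gene_span[[1]]
            out[idx] <- cs <= start(gs) & ce >= end(gs)
        }
        return(out)
    }
    ov <- pmax(0, pmin(ce, end(locus)) - pmax(cs, start(locus)) + 1)
    hit <- 2 * ov > width(locus)
    kg <- md$key_genes[[1]]
    for (i in seq_along(kg))
        hit <- hit & cs <= start(kg)[i] & ce >= end(kg)[i]
    out[idx] <- hit
    out
}

#' Write a carrier-status table
#' @param statuses output of [classifyParticipants()].
#' @param path output TSV path.
#' @export
writeCarrierStatus <- function(statuses, path) {
    utils::write.table(statuses, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}
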