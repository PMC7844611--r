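test_that("sample QC thresholds are strict: boundary samples survive", {
    qc <- rbind(mkQc("over_cnvs", n_cnvs = 31L),
                mkQc("at_cnvs", n_cnvs = 30L, waviness = 0.03,
                     call_rate = 0.96),
                mkQc("neg_wav", waviness = -0.031),
                mkQc("pos_wav", waviness = 0.031),
                mkQc("low_rate", call_rate = 0.959),
                mkQc("clean"))
    out <- filterSamples(qc)
    expect_identical(out$excluded_qc,
                     c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
    expect_identical(out$qc_reason[1], "n_cnvs")
    expect_identical(out$qc_reason[3], "waviness")
    expect_identical(out$qc_reason[5], "call_rate")
})

test_that("duplicate sample ids in QC records are a hard error naming the id", {
    qc <- rbind(mkQc("dup1"), mkQc("dup1"))
    expect_error(filterSamples(qc), "dup1")
})

test_that("call filters: probe count and density, strict at the boundary", {
    calls <- c(mkCall("chr1", 1, 50000, n_probes = 9),       # <10 probes
               mkCall("chr1", 1, 200000, n_probes = 10),     # exactly 1/20k
               mkCall("chr1", 1, 200020, n_probes = 10),     # just under
               mkCall("chr1", 1, 1000, n_probes = 10))
    out <- filterCalls(calls)
    expect_identical(mcols(out)$excluded, c(TRUE, FALSE, TRUE, FALSE))
    expect_identical(mcols(out)$filter_reason[1], "probes")
    expect_identical(mcols(out)$filter_reason[3], "density")
    bad <- mkCall("chr1", 1, 100, n_probes = 0)
    expect_error(filterCalls(bad), "n_probes")
})

test_that("multi-gene locus matching needs >half coverage and all key genes", {
    loci <- tinyLoci()
    multi <- loci["multiDel"]
    ## critical chr1:1001-2000 (1000 bp), key gene 1201-1300
    expect_true(matchLocus(mkCall("chr1", 1000, 1501), multi))  # 501 bp
    expect_false(matchLocus(mkCall("chr1", 1001, 1500), multi)) # exactly 500
    ## covers >half but clips the key gene
    expect_false(matchLocus(mkCall("chr1", 1250, 2000), multi))
    ## state and chromosome mismatches are non-matches, not errors
    expect_false(matchLocus(mkCall("chr1", 1, 3000, state = "dup"), multi))
    expect_false(matchLocus(mkCall("chr2", 1, 3000), multi))
    ## no key genes: coverage alone decides
    expect_true(matchLocus(mkCall("chr1", 5001, 5502, state = "dup"),
                           loci["plainDup"]))
})

test_that("single-gene rules: deletions touch an exon, duplications span the gene", {
    loci <- tinyLoci()
    sdel <- loci["singleDel"]; sdup <- loci["singleDup"]
    ## deletion overlapping exon 2 (chr2:14001-14300) by exactly 1 bp
    expect_true(matchLocus(mkCall("chr2", 13000, 14001), sdel))
    ## deletion inside an intron
    expect_false(matchLocus(mkCall("chr2", 11000, 13000), sdel))
    ## duplication covering the whole gene span
    expect_true(matchLocus(mkCall("chr2", 30001, 40000, state = "dup"), sdup))
    ## duplication missing the last base of the gene span
    expect_false(matchLocus(mkCall("chr2", 30001, 39999, state = "dup"), sdup))
})

test_that("classification assigns exactly one status with SCZ precedence", {
    loci <- tinyLoci()
    calls <- suppressWarnings(c(
        mkCall("chr1", 900, 2100, sample_id = "carrier1"),
        mkCall("chr1", 900, 2100, sample_id = "dualGuy"),
        mkCall("chr3", 900, 3100, sample_id = "dualGuy"),
        mkCall("chr3", 900, 3100, sample_id = "pathOnly"),
        mkCall("chr1", 900, 2100, sample_id = "qcFail"),
        mkCall("chr5", 1e6, 1.1e6, sample_id = "cleanGuy"),
        mkCall("chr1", 900, 2100, n_probes = 5, sample_id = "filteredCall")))
    qc <- rbind(mkQc("carrier1"), mkQc("dualGuy"), mkQc("pathOnly"),
                mkQc("qcFail", waviness = 0.05), mkQc("cleanGuy"),
                mkQc("filteredCall"), mkQc("noCalls"))
    st <- classifyParticipants(calls, qc, loci)
    got <- setNames(st$status, st$sample_id)
    expect_identical(got[["carrier1"]], "carrier")
    expect_identical(got[["dualGuy"]], "carrier")     # SCZ precedence
    expect_true(st$dual_carrier[st$sample_id == "dualGuy"])
    expect_identical(got[["pathOnly"]], "excluded_pathogenic")
    expect_identical(got[["qcFail"]], "excluded_qc")  # despite matching call
    expect_identical(got[["cleanGuy"]], "non_carrier")
    expect_identical(got[["filteredCall"]], "non_carrier") # call was filtered
    expect_identical(got[["noCalls"]], "non_carrier")
    expect_identical(st$matched_loci[st$sample_id == "carrier1"], "multiDel")
    ## partition: every sample exactly one status
    expect_identical(sort(st$sample_id), sort(qc$sample_id))
    expect_true(all(st$status %in% c("carrier", "non_carrier",
                                     "excluded_pathogenic", "excluded_qc")))
    ## matched_loci non-empty iff carrier
    expect_identical(st$matched_loci != "", st$status == "carrier")
})

test_that("a call for a sample missing from sample QC is a hard error", {
    loci <- tinyLoci()
    calls <- mkCall("chr1", 900, 2100, sample_id = "ghost")
    expect_error(classifyParticipants(calls, mkQc("someoneElse"), loci),
                 "ghost")
})

test_that("pre-filtering calls does not change classification", {
    loci <- tinyLoci()
    cfg <- simulationConfig(nNoncarriers = 50,
                            nCarriersPerLocus = c(multiDel = 6, singleDup = 3),
                            nExcludedByCodes = 0, nFailSampleQc = 4,
                            nPathogenic = 3, nRegions = 5,
                            callFailProbes = 10, callFailDensity = 5,
                            seed = 31)
    fx <- simulateCnvFixtures(cfg, loci)
    st_all <- classifyParticipants(fx$calls, fx$sampleQc[, 1:4], loci)
    kept <- filterCalls(fx$calls)
    kept <- kept[!mcols(kept)$excluded]
    mcols(kept)$excluded <- NULL; mcols(kept)$filter_reason <- NULL
    st_kept <- classifyParticipants(kept, fx$sampleQc[, 1:4], loci)
    expect_identical(st_all, st_kept)
})

test_that("classification recovers generator ground truth exactly", {
    loci <- tinyLoci()
    cfg <- simulationConfig(nNoncarriers = 80,
                            nCarriersPerLocus = c(multiDel = 8, plainDup = 4,
                                                  singleDel = 3),
                            nExcludedByCodes = 0, nFailSampleQc = 6,
                            nPathogenic = 5, nRegions = 5, seed = 17)
    fx <- simulateCnvFixtures(cfg, loci)
    st <- classifyParticipants(fx$calls, fx$sampleQc[, 1:4], loci)
    expect_identical(st$status, fx$sampleQc$truth_status)
})
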