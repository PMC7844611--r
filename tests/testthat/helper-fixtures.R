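suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# small locus set exercising every matching rule
tinyLoci <- function() {
    suppressWarnings(c(
        locusDefinition("multiDel", "chr1", 1001, 2000, "del",
                        keyGenes = GRanges("chr1", IRanges(1201, 1300))),
        locusDefinition("plainDup", "chr1", 5001, 6000, "dup"),
        locusDefinition("singleDel", "chr2", 10001, 20000, "del",
                        singleGene = TRUE,
                        geneSpan = GRanges("chr2", IRanges(10001, 20000)),
                        exons = GRanges("chr2",
                                        IRanges(c(10001, 14001, 19001),
                                                c(10200, 14300, 19500)))),
        locusDefinition("singleDup", "chr2", 30001, 40000, "dup",
                        singleGene = TRUE,
                        geneSpan = GRanges("chr2", IRanges(30001, 40000)),
                        exons = GRanges("chr2", IRanges(30001, 30200))),
        locusDefinition("badPath", "chr3", 1001, 3000, "del",
                        category = "pathogenic_other")))
}

mkCall <- function(chrom, start, end, state = "del", n_probes = 50,
                   sample_id = "s1") {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr) <- S4Vectors::DataFrame(sample_id = sample_id, state = state,
                                      n_probes = as.integer(n_probes))
    gr
}

mkQc <- function(sample_id, n_cnvs = 5L, waviness = 0, call_rate = 0.99) {
    data.frame(sample_id = sample_id, n_cnvs = n_cnvs, waviness = waviness,
               call_rate = call_rate, stringsAsFactors = FALSE)
}

# a small ready-made analysis dataset (carriers + non-carriers, both assays)
smallDataset <- function(nNon = 200, nCarrier = 20, seed = 42, ...) {
    cfg <- simulationConfig(
        nNoncarriers = nNon,
        nCarriersPerLocus = c("15q11.2del" = nCarrier),
        nExcludedByCodes = 0, nFailSampleQc = 0, nPathogenic = 0,
        outlierRate = 0, seed = seed, ...)
    sc <- simulateCohort(cfg)
    cc <- cohortData(sc)
    st <- data.frame(sample_id = colnames(cc),
                     status = ifelse(cohortGroups(cc) == "carrier",
                                     "carrier", "non_carrier"),
                     matched_loci = ifelse(cohortGroups(cc) == "carrier",
                                           "15q11.2del", ""),
                     dual_carrier = FALSE)
    assembleDataset(cc, st)
}

# independent naive O(m^2) BH step-up: reject i iff p_i <= p_(k*) where
# k* = max{k : p_(k) <= k q / m}
naiveBH <- function(p, q) {
    m <- length(p)
    ps <- sort(p)
    kmax <- 0L
    for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
    if (kmax == 0L) rep(FALSE, m) else p <= ps[kmax]
}

# independent OLS via normal equations
naiveOLS <- function(y, X) {
    X <- cbind(1, X)
    bh <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% bh
    s2 <- sum(res^2) / (length(y) - ncol(X))
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    list(beta = drop(bh), se = se)
}

# independent covariance-chain oracle: plain cor/atanh/means double loops
oracleZ <- function(mat) {           # mat: regions x participants
    G <- nrow(mat)
    z <- matrix(NA_real_, G, G)
    for (i in seq_len(G)) for (j in seq_len(G)) if (i != j) {
        r <- cor(mat[i, ], mat[j, ], use = "pairwise.complete.obs")
        r <- min(max(r, -(1 - 1e-12)), 1 - 1e-12)
        z[i, j] <- atanh(r)
    }
    z
}

oracleIntegration <- function(zm) {
    G <- nrow(zm)
    out <- numeric(G)
    for (i in seq_len(G)) {
        acc <- c()
        for (j in seq_len(G)) if (j != i && !is.na(zm[i, j]))
            acc <- c(acc, zm[i, j])
        out[i] <- mean(acc)
    }
    out
}

oracleOverallFromMat <- function(mat) mean(oracleIntegration(oracleZ(mat)))
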