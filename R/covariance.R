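#' @importFrom stats cor lm resid
NULL

#' Fisher z-transformed structural covariance matrix
#'
#' For every pair of regions, the Pearson correlation of the two regional
#' measures across the participants of one group is computed
#' (pairwise-complete observations) and Fisher z-transformed
#' (`atanh`). Correlations are clamped to +/-(1 - 1e-12) beforehand so
#' that degenerate perfect correlations stay finite. The diagonal is
#' `NA`. Cells with fewer than 3 pairwise-complete observations, or
#' involving a constant region, are set missing with a warning.
#'
#' @param x a [CorticalCohort-class] or a numeric regions x participants
#'   matrix.
#' @param measure assay name when `x` is a cohort.
#' @return symmetric regions x regions matrix of z values, diagonal `NA`.
#' @examples
#' m <- matrix(rnorm(300), 3, 100)
#' zm <- zMatrix(m)
#' @export
zMatrix <- function(x, measure = "thickness") {
    mat <- if (is.matrix(x)) x else assay(x, measure)
    assertThat(ncol(mat) >= 3, "need at least 3 participants")
    if (anyNA(mat)) {
        r <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
        npair <- crossprod(!is.na(t(mat)))
        r[npair < 3] <- NA
    } else {
        ## complete data: one BLAS crossprod instead of the pairwise C
        ## loop (the resampling null evaluates this tens of thousands of
        ## times); constant regions yield NaN, handled like cor()'s NA
        X <- t(mat)
        X <- X - rep(colMeans(X), each = nrow(X))
        ss <- sqrt(colSums(X * X))
        suppressWarnings(r <- crossprod(X) / tcrossprod(ss))
    }
    bad <- sum(is.na(r[upper.tri(r)]))
    if (bad > 0)
        warning(sprintf("%d region pair(s) undefined (constant region or <3 pairwise observations)",
                        bad))
    z <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
    diag(z) <- NA
    z
}

#' @rdname integrationIndex
setMethod("integrationIndex", "matrix", function(x, ...) {
    assertThat(nrow(x) == ncol(x), "z-matrix must be square")
    idx <- rowMeans(x, na.rm = TRUE)
    dead <- !is.finite(idx)
    if (any(dead)) {
        warning(sprintf("%d gyrus/gyri with no defined z values", sum(dead)))
        idx[dead] <- NA_real_
    }
    idx
})

#' Overall structural covariance
#'
#' The unweighted mean of the per-gyrus integration indices: a single
#' scalar summarizing how strongly a group's regional measures co-vary.
#'
#' @param idx numeric vector of integration indices (or a
#'   [CovarianceSummary-class]).
#' @return numeric scalar.
#' @export
overallCovariance <- function(idx) {
    if (is(idx, "CovarianceSummary")) return(idx@overall)
    assertThat(any(!is.na(idx)), "all integration indices missing")
    mean(idx, na.rm = TRUE)
}

#' Component-weighted structural covariance
#'
#' For each ICA component, the weighted mean of the per-gyrus integration
#' indices with the component's relative gyrus weights (rows of `w` sum
#' to 1, see [fitComponents()]). Gyri with a missing index are dropped
#' and the remaining weights renormalized, with a warning.
#'
#' @param idx numeric vector of integration indices.
#' @param w components x gyri weight matrix.
#' @return numeric vector, one value per component.
#' @examples
#' componentCovariance(c(0.3, 0.4, 0.5), matrix(c(2, 1, 1) / 4, 1))
#' @export
componentCovariance <- function(idx, w) {
    assertThat(ncol(w) == length(idx),
               "weight columns (%d) != number of gyri (%d)",
               ncol(w), length(idx))
    ok <- !is.na(idx)
    if (!all(ok)) {
        warning(sprintf("renormalizing weights over %d gyri with defined indices",
                        sum(ok)))
        w <- w[, ok, drop = FALSE]
        idx <- idx[ok]
        w <- w / rowSums(w)
    }
    drop(w %*% idx)
}

#' Compute the covariance summary of one group
#'
#' Convenience wrapper building a [CovarianceSummary-class]: the
#' [zMatrix()], its [integrationIndex()] and the [overallCovariance()].
#'
#' @param x cohort or regions x participants matrix (one group).
#' @param measure assay name.
#' @param group group label stored in the summary.
#' @return a [CovarianceSummary-class].
#' @export
covarianceSummary <- function(x, measure = "thickness", group = "group") {
    mat <- if (is.matrix(x)) x else assay(x, measure)
    zm <- zMatrix(mat)
    idx <- integrationIndex(zm)
    new("CovarianceSummary", measure = measure, group = group,
        n = ncol(mat), zmat = zm, integration = idx,
        overall = overallCovariance(idx))
}

# statistic evaluated on one subset of columns; identical code path for the
# carrier group and every null replicate (same clamping, same missing-data
# rules)
.covStatistic <- function(mat, statistic, weights = NULL) {
    zm <- suppressWarnings(zMatrix(mat))
    switch(statistic,
           cell = zm[lower.tri(zm)],
           integration = integrationIndex(zm),
           component = {
               assertThat(!is.null(weights),
                          "statistic 'component' needs ICA weights")
               suppressWarnings(
                   componentCovariance(integrationIndex(zm), weights))
           },
           overall = overallCovariance(integrationIndex(zm)),
           stop(sprintf("unknown statistic '%s'", statistic)))
}

#' Size-matched resampling null distribution
#'
#' Draws `B` random subsets of the non-carriers, each of exactly
#' `nCarriers` participants (simple random sampling without replacement
#' within a replicate; replicates independent), and evaluates the chosen
#' covariance statistic on each subset exactly as it is evaluated on the
#' carrier group. With `exhaustive = TRUE` all
#' `choose(n, nCarriers)` subsets are enumerated instead (small cohorts
#' only), in which case `B` is ignored.
#'
#' @param x non-carrier cohort or regions x participants matrix.
#' @param nCarriers carrier-group size; must be below the non-carrier
#'   count.
#' @param B replicate count.
#' @param statistic one of `"overall"`, `"integration"`, `"component"`,
#'   `"cell"`.
#' @param seed RNG seed; the replicate stream is reproducible from it.
#' @param measure assay name when `x` is a cohort.
#' @param weights ICA weight matrix (required for
#'   `statistic = "component"`).
#' @param exhaustive enumerate all subsets instead of sampling.
#' @return a [NullDistribution-class].
#' @export
resampleNull <- function(x, nCarriers, B = 1000L,
                         statistic = c("overall", "integration",
                                       "component", "cell"),
                         seed = 1L, measure = "thickness", weights = NULL,
                         exhaustive = FALSE) {
    statistic <- match.arg(statistic)
    mat <- if (is.matrix(x)) x else assay(x, measure)
    n <- ncol(mat)
    assertThat(nCarriers < n,
               "carrier-group size (%d) must be below the non-carrier count (%d)",
               nCarriers, n)
    assertThat(nCarriers >= 3, "need at least 3 participants per subset")
    if (exhaustive) {
        nsub <- choose(n, nCarriers)
        assertThat(nsub <= 1e5,
                   "%.0f subsets is too many to enumerate", nsub)
        subsets <- utils::combn(n, nCarriers)
        vals <- t(apply(subsets, 2, function(ii)
            .covStatistic(mat[, ii, drop = FALSE], statistic, weights)))
        if (nsub == 1L || length(vals) == nsub) vals <- matrix(vals, ncol = 1)
        return(new("NullDistribution", statistic = statistic,
                   B = as.integer(nsub), values = vals,
                   seed = as.integer(seed)))
    }
    assertThat(B >= 1, "B must be >= 1")
    d <- length(.covStatistic(mat[, seq_len(nCarriers), drop = FALSE],
                              statistic, weights))
    vals <- matrix(NA_real_, B, d)
    withSeed(seed, {
        for (b in seq_len(B)) {
            ii <- sample.int(n, nCarriers)
            vals[b, ] <- .covStatistic(mat[, ii, drop = FALSE], statistic,
                                       weights)
        }
    })
    new("NullDistribution", statistic = statistic, B = as.integer(B),
        values = vals, seed = as.integer(seed))
}

#' Empirical p-value by absolute exceedance counting
#'
#' The empirical p-value is the fraction of null replicates whose
#' statistic exceeds the observed one in absolute value (strict
#' exceedance). With `smoothed = TRUE` the positively biased estimator
#' `(count + 1) / (B + 1)` is returned instead, which never reports
#' exactly zero.
#'
#' @param null a [NullDistribution-class] (or numeric vector/matrix of
#'   null values).
#' @param observed observed statistic, same dimension as one null
#'   replicate.
#' @param smoothed use the `(count + 1) / (B + 1)` estimator.
#' @return numeric vector of p-values (length = statistic dimension).
#' @examples
#' empiricalP(c(0.1, 0.2, 0.3, 0.9), 0.5)   # 0.25
#' @export
empiricalP <- function(null, observed, smoothed = FALSE) {
    vals <- if (is(null, "NullDistribution")) nullValues(null) else null
    if (!is.matrix(vals)) vals <- matrix(vals, ncol = 1)
    assertThat(length(observed) == ncol(vals),
               "observed statistic dimension (%d) != null dimension (%d)",
               length(observed), ncol(vals))
    B <- nrow(vals)
    cnt <- colSums(abs(vals) > rep(abs(observed), each = B))
    if (smoothed) (cnt + 1) / (B + 1) else cnt / B
}

#' Compare structural covariance between carriers and non-carriers
#'
#' For each measure this computes the carrier and non-carrier
#' [covarianceSummary()], fits the ICA component weights on the pooled
#' standardized table (both groups, one fit, so both are evaluated on
#' identical components), computes the per-component covariance of both
#' groups, and compares the carrier statistics against a size-matched
#' resampling null over the non-carriers ([resampleNull()]): empirical
#' p-values for the overall value, each gyrus's integration index, each
#' component and (optionally) each pairwise cell. Per-gyrus and
#' per-component p-values are FDR-flagged with [bhFdr()] at level `q`.
#'
#' By default correlations are computed on the raw measures; with
#' `residualize = TRUE` the association covariates are regressed out of
#' every region (complete-case, pooled sample) first.
#'
#' @param dataset a [CorticalCohort-class] with `group` labels `carrier` /
#'   `non_carrier` ([assembleDataset()]).
#' @param measures assays to analyse.
#' @param B null replicates per measure (100,000 reproduces the p
#'   granularity of a large-scale run; use ~1,000 for exploration).
#' @param k ICA component count (default 20).
#' @param seed base RNG seed; measure `m` uses `seed + m - 1`.
#' @param q FDR level for per-gyrus and per-component flags.
#' @param includeCell also derive per-cell empirical p-values.
#' @param residualize regress covariates out before correlating.
#' @param covariates covariates used when `residualize = TRUE`.
#' @param smoothed use smoothed empirical p-values.
#' @return named list (one entry per measure), each with elements
#'   `carriers`, `noncarriers` ([CovarianceSummary-class]), `weights`,
#'   `componentValues` (2 x k), `p` (list: `overall`, `integration`,
#'   `component`, optionally `cell`), `fdr` (flags for integration and
#'   component), and `null` (the overall-statistic
#'   [NullDistribution-class]).
#' @export
compareGroups <- function(dataset,
                          measures = assayNames(dataset),
                          B = 1000L, k = 20, seed = 1L, q = 0.10,
                          includeCell = FALSE, residualize = FALSE,
                          covariates = c("age", "sex", "icv", "centre"),
                          smoothed = FALSE) {
    g <- cohortGroups(dataset)
    assertThat(!is.null(g) && all(c("carrier", "non_carrier") %in% g),
               "dataset must contain both 'carrier' and 'non_carrier' groups")
    out <- list()
    for (mi in seq_along(measures)) {
        m <- measures[mi]
        mat <- assay(dataset, m)
        if (residualize)
            mat <- .residualizeRegions(mat, colData(dataset), covariates)
        carr <- mat[, g == "carrier", drop = FALSE]
        nonc <- mat[, g == "non_carrier", drop = FALSE]

        cs <- covarianceSummary(carr, m, "carrier")
        ns <- covarianceSummary(nonc, m, "non_carrier")
        pooled <- mat[, g %in% c("carrier", "non_carrier"), drop = FALSE]
        wts <- fitComponents(pooled, k = k, seed = seed + mi - 1L)
        compv <- rbind(carrier = componentCovariance(integrationIndex(cs), wts),
                       non_carrier = componentCovariance(integrationIndex(ns),
                                                         wts))

        obs <- list(overall = overallValue(cs),
                    integration = integrationIndex(cs),
                    component = compv["carrier", ])
        if (includeCell) obs$cell <- zMat(cs)[lower.tri(zMat(cs))]

        ## one pass over the replicates, all statistics at once
        cnt <- lapply(obs, function(o) numeric(length(o)))
        overall_null <- numeric(B)
        withSeed(seed + mi - 1L, {
            for (b in seq_len(B)) {
                ii <- sample.int(ncol(nonc), ncol(carr))
                zm <- suppressWarnings(zMatrix(nonc[, ii, drop = FALSE]))
                idx <- integrationIndex(zm)
                reps <- list(overall = overallCovariance(idx),
                             integration = idx,
                             component = suppressWarnings(
                                 componentCovariance(idx, wts)))
                if (includeCell) reps$cell <- zm[lower.tri(zm)]
                for (s in names(cnt))
                    cnt[[s]] <- cnt[[s]] +
                        (abs(reps[[s]]) > abs(obs[[s]]) & !is.na(reps[[s]]))
                overall_null[b] <- reps$overall
            }
        })
        p <- lapply(cnt, function(cc)
            if (smoothed) (cc + 1) / (B + 1) else cc / B)
        fdr <- list(integration = bhFdr(p$integration, q = q),
                    component = bhFdr(p$component, q = q))

        out[[m]] <- list(
            carriers = cs, noncarriers = ns, weights = wts,
            componentValues = compv, p = p, fdr = fdr,
            null = new("NullDistribution", statistic = "overall",
                       B = as.integer(B),
                       values = matrix(overall_null, ncol = 1),
                       seed = as.integer(seed + mi - 1L)))
    }
    out
}

.residualizeRegions <- function(mat, cd, covariates) {
    cd <- as.data.frame(cd)
    missing_cov <- setdiff(covariates, names(cd))
    assertThat(length(missing_cov) == 0, "unknown covariate(s): %s",
               paste(missing_cov, collapse = ", "))
    X <- cd[, covariates, drop = FALSE]
    for (r in seq_len(nrow(mat))) {
        df <- data.frame(y = mat[r, ], X)
        cc <- complete.cases(df)
        fit <- lm(y ~ ., data = df[cc, , drop = FALSE])
        row <- rep(NA_real_, ncol(mat))
        row[cc] <- resid(fit)
        mat[r, ] <- row
    }
    mat
}
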