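test_that("z-matrix cells are Fisher-transformed correlations with clamping", {
    ## exact r = 0.5 via constructed columns
    x <- c(1, 2, 3, 4, 5, 6)
    y <- x * 0.5 + c(1.2, -0.8, -1.3, 1.0, -0.1, 0) # engineered noise
    r <- cor(x, y)
    m <- rbind(g1 = x, g2 = y)
    colnames(m) <- paste0("p", 1:6)
    zm <- zMatrix(m)
    expect_equal(zm["g1", "g2"], atanh(r), tolerance = 1e-12)
    expect_true(is.na(zm["g1", "g1"]))
    expect_equal(zm, t(zm))

    ## duplicated region: r = 1 clamps to a finite z > 13
    m2 <- rbind(g1 = x, g2 = x, g3 = y); colnames(m2) <- paste0("p", 1:6)
    zm2 <- zMatrix(m2)
    expect_true(is.finite(zm2["g1", "g2"]))
    expect_gt(zm2["g1", "g2"], 13)

    ## independent long columns have near-zero z
    set.seed(4)
    m3 <- rbind(a = rnorm(10000), b = rnorm(10000))
    colnames(m3) <- sprintf("p%05d", 1:10000)
    expect_lt(abs(zMatrix(m3)["a", "b"]), 0.05)

    ## constant region: affected cells missing, with a warning
    m4 <- rbind(g1 = x, g2 = rep(1, 6)); colnames(m4) <- paste0("p", 1:6)
    expect_warning(zm4 <- zMatrix(m4), "undefined")
    expect_true(is.na(zm4["g1", "g2"]))
})

test_that("integration and overall indices match hand and brute-force values", {
    zm <- matrix(NA_real_, 3, 3)
    zm[1, 2] <- zm[2, 1] <- 0.2
    zm[1, 3] <- zm[3, 1] <- 0.4
    zm[2, 3] <- zm[3, 2] <- 0.6
    idx <- integrationIndex(zm)
    expect_equal(unname(idx), c(0.3, 0.4, 0.5))
    expect_equal(overallCovariance(idx), 0.4)

    ## constant off-diagonal
    zc <- matrix(0.7, 4, 4); diag(zc) <- NA
    expect_equal(unname(integrationIndex(zc)), rep(0.7, 4))

    ## oracle equivalence on random symmetric matrices
    set.seed(9)
    for (i in 1:10) {
        a <- matrix(rnorm(100), 10, 10)
        zm <- (a + t(a)) / 2; diag(zm) <- NA
        expect_equal(unname(integrationIndex(zm)), oracleIntegration(zm),
                     tolerance = 1e-10)
    }

    ## permutation invariance of the overall value
    perm <- sample(10)
    a <- matrix(rnorm(100), 10, 10); zm <- (a + t(a)) / 2; diag(zm) <- NA
    expect_equal(overallCovariance(integrationIndex(zm[perm, perm])),
                 overallCovariance(integrationIndex(zm)), tolerance = 1e-12)
    expect_error(overallCovariance(rep(NA_real_, 3)), "missing")
})

test_that("component covariance is the weighted mean of integration indices", {
    idx <- c(0.3, 0.4, 0.5)
    expect_equal(componentCovariance(idx, matrix(c(2, 1, 1) / 4, 1)), 0.375)
    ## one-hot weights pick out a single gyrus
    w <- diag(3)
    expect_equal(unname(componentCovariance(idx, w)), idx)
    ## uniform weights reduce to the overall value
    wu <- matrix(1 / 3, 2, 3)
    expect_equal(unname(componentCovariance(idx, wu)),
                 rep(overallCovariance(idx), 2), tolerance = 1e-12)
    ## missing indices: renormalize and warn
    expect_warning(v <- componentCovariance(c(0.3, NA, 0.5),
                                            matrix(c(2, 1, 1) / 4, 1)),
                   "renormalizing")
    expect_equal(unname(v), (2 * 0.3 + 1 * 0.5) / 3)
    expect_error(componentCovariance(idx, matrix(1, 1, 2)), "gyri")
})

test_that("ICA weights are normalized, seeded, and recover disjoint sources", {
    set.seed(2)
    n <- 600
    S <- matrix(runif(n * 3, -sqrt(3), sqrt(3)), n, 3)  # sub-Gaussian sources
    A <- matrix(0, 3, 12)
    A[1, 1:4] <- c(1.0, 0.8, 0.9, 0.7)
    A[2, 5:8] <- c(0.9, 1.0, 0.6, 0.8)
    A[3, 9:12] <- c(0.7, 0.9, 1.0, 0.8)
    X <- S %*% A + matrix(rnorm(n * 12, sd = 0.05), n, 12)
    mat <- t(X); rownames(mat) <- paste0("g", 1:12)
    colnames(mat) <- sprintf("p%04d", 1:n)

    w <- fitComponents(mat, k = 3, seed = 5)
    expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(w >= 0))
    w2 <- fitComponents(mat, k = 3, seed = 5)
    expect_identical(w, w2)

    ## each component's top-4 gyri coincide with one true source block
    blocks <- list(1:4, 5:8, 9:12)
    tops <- lapply(1:3, function(c) sort(order(w[c, ],
                                               decreasing = TRUE)[1:4]))
    matched <- vapply(tops, function(tp)
        any(vapply(blocks, identical, logical(1), tp)), logical(1))
    expect_true(all(matched))
})

test_that("non-convergent ICA warns by default and errors in strict mode", {
    set.seed(6)
    g <- matrix(rnorm(3000), 100, 30)   # Gaussian: contrast surface flat
    mat <- t(g); rownames(mat) <- paste0("g", 1:30)
    colnames(mat) <- paste0("p", 1:100)
    expect_warning(fitComponents(mat, k = 8, seed = 1, maxit = 5),
                   "did not converge")
    expect_error(fitComponents(mat, k = 8, seed = 1, maxit = 5,
                               onNoConvergence = "error"),
                 "did not converge")
})

test_that("resampling null is seeded and matches exhaustive enumeration", {
    set.seed(14)
    mat <- matrix(rnorm(7 * 4), 4, 7,
                  dimnames = list(paste0("g", 1:4), paste0("p", 1:7)))
    a <- resampleNull(mat, nCarriers = 3, B = 10, statistic = "overall",
                      seed = 99)
    b <- resampleNull(mat, nCarriers = 3, B = 10, statistic = "overall",
                      seed = 99)
    expect_identical(nullValues(a), nullValues(b))

    ## exhaustive: all 7-choose-3 subsets, against an independent oracle
    ex <- resampleNull(mat, nCarriers = 3, statistic = "overall",
                       exhaustive = TRUE)
    expect_equal(ex@B, 35L)
    oracle <- apply(combn(7, 3), 2, function(ii)
        oracleOverallFromMat(mat[, ii]))
    expect_equal(sort(drop(nullValues(ex))), sort(oracle), tolerance = 1e-10)

    expect_error(resampleNull(mat, nCarriers = 7, B = 5), "below")
})

test_that("empirical p counts strict absolute exceedance", {
    expect_equal(empiricalP(c(0.1, 0.2, 0.3, 0.9), 0.5), 0.25)
    expect_equal(empiricalP(c(0.1, 0.2, 0.3, 0.9), 1.5), 0)
    expect_equal(empiricalP(c(0.1, 0.2, 0.3, 0.9), 1.5, smoothed = TRUE),
                 1 / 5)
    expect_equal(empiricalP(c(0.1, 0.2, -0.3, 0.9), 0), 1)
    ## sign-flip invariance of both null and observed
    set.seed(3)
    nulls <- rnorm(200); obs <- 0.4
    expect_equal(empiricalP(nulls, obs), empiricalP(-nulls, obs))
    expect_equal(empiricalP(nulls, obs), empiricalP(nulls, -obs))
    ## matrix nulls: one p per column
    nv <- cbind(c(0.1, 0.2, 0.3, 0.9), c(1, 1, 1, 1))
    expect_equal(empiricalP(nv, c(0.5, 2)), c(0.25, 0))
    expect_error(empiricalP(nv, 0.5), "dimension")
})

test_that("atanh monotonicity: stronger correlation raises z and the indices", {
    set.seed(21)
    f <- rnorm(300)
    mk <- function(b) {
        m <- t(b * f + matrix(rnorm(300 * 6), 300, 6))
        rownames(m) <- paste0("g", 1:6); colnames(m) <- paste0("p", 1:300)
        m
    }
    lo <- covarianceSummary(mk(0.4)); hi <- covarianceSummary(mk(1.2))
    expect_gt(overallValue(hi), overallValue(lo))
    expect_true(all(integrationIndex(hi) > integrationIndex(lo)))
})

test_that("group comparison is deterministic and self-consistent", {
    ds <- smallDataset(nNon = 120, nCarrier = 15, nRegions = 12L)
    cv1 <- suppressWarnings(compareGroups(ds, measures = "thickness",
                                          B = 40, k = 3, seed = 8))
    cv2 <- suppressWarnings(compareGroups(ds, measures = "thickness",
                                          B = 40, k = 3, seed = 8))
    expect_identical(cv1$thickness$p, cv2$thickness$p)
    expect_identical(nullValues(cv1$thickness$null),
                     nullValues(cv2$thickness$null))
    res <- cv1$thickness
    expect_s4_class(res$carriers, "CovarianceSummary")
    expect_equal(dim(res$componentValues), c(2, 3))
    expect_length(res$p$integration, 12)
    expect_length(res$p$component, 3)
    expect_true(all(res$p$overall >= 0 & res$p$overall <= 1))
    ## component values of each group: weighted means of that group's indices
    expect_equal(unname(res$componentValues["carrier", ]),
                 unname(componentCovariance(integrationIndex(res$carriers),
                                            res$weights)))
})
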