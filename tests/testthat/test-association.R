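mkAssocCohort <- function(n = 100, seed = 1, yfun) {
    set.seed(seed)
    nc <- n %/% 4
    carrier <- rep(c(1, 0), c(nc, n - nc))
    age <- runif(n, 45, 80)
    age_z <- (age - mean(age)) / sd(age)
    icv <- rnorm(n, 1.5e6, 1e5)
    sex <- rbinom(n, 1, 0.5); centre <- rbinom(n, 1, 0.2)
    y <- yfun(carrier, age_z, sex, icv, centre)
    m <- rbind(regionA = y, regionB = rnorm(n) + 2)
    colnames(m) <- sprintf("p%03d", 1:n)
    cov <- data.frame(participant_id = colnames(m),
                      group = ifelse(carrier == 1, "carrier", "non_carrier"),
                      age = age, sex = sex, icv = icv, centre = centre)
    corticalCohort(list(thickness = m), cov)
}

test_that("noiseless linear outcomes are recovered exactly", {
    cc <- mkAssocCohort(100, 1, function(carrier, age_z, sex, icv, centre)
        0.5 * carrier + 0.2 * age_z)
    r <- suppressWarnings(   # perfect fit: zero residual variance
        fitMeasure(cc, "regionA", "thickness", covariates = c("age"),
                   standardize = FALSE))
    expect_equal(r$beta, 0.5, tolerance = 1e-10)
    expect_lt(r$se, 1e-10)
})

test_that("OLS matches an independent normal-equations solve", {
    cc <- mkAssocCohort(80, 3, function(carrier, age_z, sex, icv, centre)
        0.3 * carrier - 0.1 * sex + rnorm(length(carrier)))
    r <- fitMeasure(cc, "regionA", "thickness",
                    covariates = c("age", "sex", "icv", "centre"),
                    standardize = FALSE)
    cd <- as.data.frame(colData(cc))
    X <- cbind(carrier = as.numeric(cd$group == "carrier"),
               age = cd$age, sex = cd$sex, icv = cd$icv, centre = cd$centre)
    o <- naiveOLS(assay(cc, "thickness")["regionA", ], X)
    expect_equal(r$beta, unname(o$beta["carrier"]), tolerance = 1e-10)
    expect_equal(r$se, unname(o$se[2]), tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
    cc <- mkAssocCohort(50, 2, function(carrier, ...) rep(1, length(carrier)))
    expect_error(fitMeasure(cc, "regionA", "thickness"), "zero variance")

    cc2 <- mkAssocCohort(50, 2, function(carrier, ...) rnorm(length(carrier)))
    cd <- colData(cc2); cd$age2 <- 2 * cd$age
    SummarizedExperiment::colData(cc2) <- cd
    expect_error(fitMeasure(cc2, "regionA", "thickness",
                            covariates = c("age", "age2"), standardize = FALSE),
                 "collinear.*age2")
    expect_error(fitMeasure(cc2, "regionA", "thickness",
                            contrast = c("carrier", "ghosts")), "ghosts")
})

test_that("adding an orthogonal covariate leaves a noiseless beta unchanged", {
    cc <- mkAssocCohort(100, 4, function(carrier, age_z, ...) 0.5 * carrier)
    cd <- colData(cc)
    carrier <- as.numeric(cd$group == "carrier")
    ortho <- rnorm(100)
    ortho <- resid(lm(ortho ~ carrier))        # exactly orthogonal
    cd$ortho <- ortho
    SummarizedExperiment::colData(cc) <- cd
    r0 <- suppressWarnings(fitMeasure(cc, "regionA", "thickness",
                                      covariates = character(0),
                                      standardize = FALSE))
    r1 <- suppressWarnings(fitMeasure(cc, "regionA", "thickness",
                                      covariates = "ortho",
                                      standardize = FALSE))
    expect_equal(r1$beta, r0$beta, tolerance = 1e-10)
})

test_that("BH step-up matches hand-computed and oracle results", {
    expect_identical(bhFdr(c(0.01, 0.02, 0.03, 0.04), q = 0.10,
                           familySize = 4), rep(TRUE, 4))
    expect_identical(bhFdr(rep(1, 5)), rep(FALSE, 5))
    expect_identical(bhFdr(0.09, q = 0.10, familySize = 1), TRUE)
    expect_error(bhFdr(c(0.1, 0.2), familySize = 3), "familySize")
    expect_error(bhFdr(c(0.1, NA)), "p-values")

    set.seed(11)
    for (i in 1:50) {
        m <- sample(1:40, 1)
        p <- runif(m)^sample(1:3, 1)
        q <- runif(1, 0.01, 0.3)
        flags <- bhFdr(p, q = q, familySize = m)
        expect_identical(flags, naiveBH(p, q))
        ## monotone in p
        if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
    }
})

test_that("runFamily builds the overall and 136-test regional families", {
    ds <- smallDataset(nNon = 150, nCarrier = 12)
    res <- runFamily(ds, regional = TRUE)
    overall <- res[res$family == "overall", ]
    ## one contrast (the single locus has >2 carriers => also per-locus)
    expect_equal(nrow(overall), 2 * 2)          # 2 contrasts x 2 measures
    reg <- res[startsWith(res$family, "regional:carrier"), ]
    expect_equal(nrow(reg), 68 * 2)             # the 136-test family
    expect_true(all(table(res$family[startsWith(res$family, "regional")]) ==
                    136))
    ## declared family size is enforceable
    res12 <- runFamily(ds, regional = FALSE, overallFamilySize = 4)
    expect_equal(nrow(res12[res12$family == "overall", ]), 4)
})

test_that("per-CNV contrasts with too few carriers are refused", {
    ds <- smallDataset(nNon = 100, nCarrier = 10)
    ## pretend only 2 carriers carry a rare locus
    cd <- colData(ds)
    idx <- which(cd$group == "carrier")
    cd$matched_loci[idx[1:2]] <- "rareLocus"
    SummarizedExperiment::colData(ds) <- cd
    expect_error(runFamily(ds, contrasts = list(c("rareLocus", "non_carrier")),
                           regional = FALSE), ">2")
})

test_that("carrier effect recovery: beta lands within 2 SE of delta", {
    cfg <- simulationConfig(
        nNoncarriers = 940, nCarriersPerLocus = c(locusA = 60),
        nExcludedByCodes = 0, nFailSampleQc = 0, nPathogenic = 0,
        nRegions = 4, measures = "thickness",
        meanShift = list(thickness = c(locusA = -0.3)),
        factorLoading = list(thickness = c(carrier = 0, non_carrier = 0)),
        covariateEffects = list(thickness = c(age = 0, sex = 0, icv = 0,
                                              centre = 0)),
        outlierRate = 0, seed = 88)
    sc <- simulateCohort(cfg)
    cc <- cohortData(sc)
    st <- data.frame(sample_id = colnames(cc),
                     status = ifelse(cohortGroups(cc) == "carrier",
                                     "carrier", "non_carrier"),
                     matched_loci = "", dual_carrier = FALSE)
    ds <- assembleDataset(cc, st)
    r <- fitMeasure(ds, "region01", "thickness")
    expect_lt(abs(r$beta - (-0.3)), 2 * r$se)
})
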