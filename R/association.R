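#' @importFrom stats lm coef pt p.adjust complete.cases model.matrix
NULL

#' Regress one cortical measure on carrier status
#'
#' Ordinary least squares of an outcome (one region, or a whole-brain
#' summary) on a carrier indicator plus covariates, complete-case per
#' outcome. The reported `beta` is the carrier coefficient with its
#' standard error and a two-sided p-value from the t distribution.
#'
#' With `standardize = TRUE` (default) the outcome and all continuous
#' covariates are z-scored over the analysis rows, so betas are in
#' outcome-SD units and comparable across regions and measures; binary
#' covariates (sex, centre) and the carrier indicator are left on their
#' 0/1 scale.
#'
#' @param dataset a [CorticalCohort-class] with a `group` covariate (see
#'   [assembleDataset()]).
#' @param outcome a region name (row of the assay), or `"total"` for the
#'   whole-brain summary: mean across regions for thickness, sum for
#'   surface area.
#' @param measure assay name.
#' @param contrast length-2 character: groups coded 1 and 0. Groups may be
#'   `"carrier"`/`"non_carrier"` or any label in `matched_loci`-derived
#'   columns; participants in neither group are dropped. Default
#'   `c("carrier", "non_carrier")`.
#' @param covariates character vector of colData columns to adjust for.
#'   Default `c("age", "sex", "icv", "centre")`; drop `"icv"` to
#'   reproduce head-size-unadjusted analyses, append e.g. ancestry PCs to
#'   extend.
#' @param standardize z-score the outcome and continuous covariates.
#' @return one-row data.frame: `outcome`, `measure`, `contrast`, `beta`,
#'   `se`, `t`, `p`, `n_used`.
#' @export
fitMeasure <- function(dataset, outcome, measure = "thickness",
                       contrast = c("carrier", "non_carrier"),
                       covariates = c("age", "sex", "icv", "centre"),
                       standardize = TRUE) {
    assertThat(length(contrast) == 2, "contrast must name exactly two groups")
    y <- .outcomeVector(dataset, outcome, measure)
    grp <- .contrastGroups(dataset, contrast)
    keep <- !is.na(grp)
    cd <- as.data.frame(colData(dataset))
    missing_cov <- setdiff(covariates, names(cd))
    assertThat(length(missing_cov) == 0, "unknown covariate(s): %s",
               paste(missing_cov, collapse = ", "))
    df <- data.frame(y = y[keep], carrier = grp[keep],
                     cd[keep, covariates, drop = FALSE])
    df <- df[complete.cases(df), , drop = FALSE]
    assertThat(min(table(df$carrier)) >= 2,
               "need at least 2 participants per contrast level")
    assertThat(sd(df$y) > 0, "outcome '%s' has zero variance", outcome)

    if (standardize) {
        df$y <- zstd(df$y, outcome)
        for (v in covariates) {
            x <- df[[v]]
            if (is.numeric(x) && length(unique(x)) > 2)
                df[[v]] <- zstd(x, v)
        }
    }
    .checkCollinear(df, covariates)
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    assertThat("carrier" %in% rownames(sm), "carrier term dropped from fit")
    data.frame(outcome = outcome, measure = measure,
               contrast = paste(contrast, collapse = " vs "),
               beta = sm["carrier", 1], se = sm["carrier", 2],
               t = sm["carrier", 3], p = sm["carrier", 4],
               n_used = nrow(df), stringsAsFactors = FALSE)
}

.outcomeVector <- function(dataset, outcome, measure) {
    assertThat(measure %in% assayNames(dataset),
               "no assay '%s' in dataset", measure)
    mat <- assay(dataset, measure)
    if (identical(outcome, "total")) {
        ## whole-brain summary over the available regions (outlier removal
        ## leaves scattered missing values): mean thickness, total area
        ## rescaled to the full region count
        m <- colMeans(mat, na.rm = TRUE)
        if (measure == "surface_area") m * nrow(mat) else m
    } else {
        assertThat(outcome %in% rownames(mat), "unknown region '%s'", outcome)
        mat[outcome, ]
    }
}

# carrier indicator: 1 for contrast[1], 0 for contrast[2], NA otherwise.
# Group labels are matched against the analysis group and, for per-locus
# contrasts, against matched_loci entries.
.contrastGroups <- function(dataset, contrast) {
    cd <- colData(dataset)
    g <- as.character(cd$group)
    lab <- function(target) {
        hit <- g == target
        if (!any(hit) && "matched_loci" %in% colnames(cd)) {
            ml <- splitCodes(as.character(cd$matched_loci))
            hit <- vapply(ml, function(v) target %in% v, logical(1)) &
                g == "carrier"
        }
        hit
    }
    in1 <- lab(contrast[1]); in0 <- lab(contrast[2])
    assertThat(any(in1), "empty contrast level '%s'", contrast[1])
    assertThat(any(in0), "empty contrast level '%s'", contrast[2])
    out <- rep(NA_real_, length(g))
    out[in0] <- 0; out[in1] <- 1
    out
}

.checkCollinear <- function(df, covariates) {
    mm <- model.matrix(~ ., data = df[, setdiff(names(df), "y"), drop = FALSE])
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm)) {
        dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
        stop(sprintf("collinear covariates: %s is a linear combination of the others",
                     paste(dropped, collapse = ", ")), call. = FALSE)
    }
    invisible(TRUE)
}

#' Benjamini-Hochberg FDR flags over one test family
#'
#' Step-up BH procedure at level `q` over exactly `familySize` tests. The
#' family size must equal the number of p-values supplied: correcting a
#' family over a silently different number of tests is the classic way
#' multiple-testing control drifts, so the mismatch is a hard error.
#'
#' @param p numeric vector of two-sided p-values.
#' @param q FDR level (default 0.10).
#' @param familySize declared number of tests in the family.
#' @return logical vector of rejection flags, monotone in `p`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04), q = 0.10, familySize = 4)
#' @export
bhFdr <- function(p, q = 0.10, familySize = length(p)) {
    assertThat(q > 0 && q < 1, "q must be in (0, 1)")
    assertThat(!anyNA(p) && all(p >= 0 & p <= 1),
               "p-values must be present and in [0, 1]")
    assertThat(familySize == length(p),
               "familySize (%d) != number of p-values (%d)",
               familySize, length(p))
    p.adjust(p, method = "BH") <= q
}

#' Run the configured families of association tests
#'
#' For each requested contrast this runs the whole-brain (`"total"`)
#' models and, when `regional = TRUE`, every region x measure model, and
#' applies [bhFdr()] within the families the analysis defines: one family
#' across all whole-brain tests (its declared size is configurable, since
#' the same whole-brain battery can be counted with or without the
#' any-carrier rows), and one family of 68 regions x 2 measures = 136
#' tests per contrast.
#'
#' Per-locus contrasts are only fitted for loci with more than 2 carriers;
#' requesting a sparser locus is refused.
#'
#' @param dataset a [CorticalCohort-class] from [assembleDataset()].
#' @param contrasts list of length-2 character vectors (each a contrast as
#'   in [fitMeasure()]); the default compares any-carrier and each locus
#'   with >2 carriers against non-carriers.
#' @param measures assays to test.
#' @param covariates,standardize passed to [fitMeasure()].
#' @param q FDR level (default 0.10).
#' @param overallFamilySize declared size of the whole-brain family;
#'   default = number of whole-brain tests actually run.
#' @param regional run the per-region families too.
#' @return data.frame of [fitMeasure()] rows plus `family` and `fdr_flag`.
#' @export
runFamily <- function(dataset, contrasts = NULL,
                      measures = assayNames(dataset),
                      covariates = c("age", "sex", "icv", "centre"),
                      standardize = TRUE, q = 0.10,
                      overallFamilySize = NULL, regional = TRUE) {
    cd <- colData(dataset)
    if (is.null(contrasts)) {
        contrasts <- list(c("carrier", "non_carrier"))
        if ("matched_loci" %in% colnames(cd)) {
            ml <- unlist(splitCodes(as.character(
                cd$matched_loci[cd$group == "carrier"])))
            tab <- table(ml[ml != ""])
            for (locus in names(tab)[tab > 2])
                contrasts <- c(contrasts, list(c(locus, "non_carrier")))
        }
    } else {
        for (ct in contrasts) .assertContrastSize(dataset, ct)
    }

    fit1 <- function(ct, outcome, m)
        fitMeasure(dataset, outcome, m, contrast = ct,
                   covariates = covariates, standardize = standardize)

    overall <- do.call(rbind, lapply(contrasts, function(ct)
        do.call(rbind, lapply(measures, function(m) fit1(ct, "total", m)))))
    overall$family <- "overall"
    fs <- if (is.null(overallFamilySize)) nrow(overall) else overallFamilySize
    overall$fdr_flag <- bhFdr(overall$p, q = q, familySize = fs)

    out <- overall
    if (regional) {
        regions <- rownames(dataset)
        for (ct in contrasts) {
            fam <- do.call(rbind, lapply(measures, function(m)
                do.call(rbind, lapply(regions, function(r) fit1(ct, r, m)))))
            fam$family <- paste0("regional:", paste(ct, collapse = " vs "))
            fam$fdr_flag <- bhFdr(fam$p, q = q, familySize = nrow(fam))
            out <- rbind(out, fam)
        }
    }
    rownames(out) <- NULL
    out
}

# per-locus contrasts need > 2 carriers
.assertContrastSize <- function(dataset, contrast) {
    cd <- colData(dataset)
    for (side in contrast) {
        if (side %in% c("carrier", "non_carrier")) next
        ml <- splitCodes(as.character(cd$matched_loci))
        n <- sum(vapply(ml, function(v) side %in% v, logical(1)) &
                 cd$group == "carrier")
        assertThat(n > 2,
            "contrast '%s' has only %d carriers; per-CNV analyses need >2",
            side, n)
    }
    invisible(TRUE)
}
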