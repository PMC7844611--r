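Package: cnvCortex
Title: CNV Carrier Classification and Cortical Structural Covariance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control and locus matching for PennCNV-style copy number
    variant (CNV) calls, classification of participants as carriers of
    schizophrenia-associated CNVs, preparation of Desikan-Killiany regional
    cortical thickness and surface-area tables, mass-univariate association
    of cortical measures with carrier status under Benjamini-Hochberg FDR
    control, and comparison of Fisher z-transformed structural covariance
    networks between groups using a size-matched resampling null with
    empirical p-values and ICA-component-weighted regional statistics.
    Includes a synthetic-cohort generator with a latent-factor covariance
    model for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: CopyNumberVariation, QualityControl, StatisticalMethod, Regression
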