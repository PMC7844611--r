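---
title: "Methods: CNV carrier status and cortical structural covariance"
author: "cnvCortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV carrier status and cortical structural covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific background

Rare copy number variants (CNVs) that confer high risk for schizophrenia
are carried by a small fraction of the general population, most of whom
never develop the disorder. Comparing the cortical anatomy of unaffected
carriers against non-carriers isolates the effect of genetic risk from the
confounds of illness (medication, chronicity, substance use). cnvCortex
implements the full analytic chain for such a study on per-sample CNV call
tables and Desikan–Killiany (D–K) regional morphometry tables:

1. **CNV quality control and carrier classification** — sample- and
   call-level filters in the PennCNV dialect, locus matching against
   critical-region definitions, and a four-way participant classification.
2. **Phenotype preparation** — diagnosis-code exclusion, extreme-value
   removal, dataset assembly.
3. **Mass-univariate association** — OLS regression of each cortical
   measure on carrier status with covariates, under Benjamini–Hochberg
   (BH) FDR control within declared test families.
4. **Structural covariance comparison** — Fisher-z correlation matrices,
   per-gyrus integration indices, overall and ICA-component-weighted
   covariance, compared between groups via a size-matched resampling null
   with empirical p-values.
5. **A synthetic-cohort generator** that produces cohorts with exactly
   the statistical structure the analysis assumes, so every stage is
   testable end to end without restricted cohort data.

## CNV quality control

A sample is excluded when it has more than 30 CNV calls, |waviness| above
0.03, or a call rate below 96%; a call is excluded when covered by fewer
than 10 probes or by fewer than 1 probe per 20,000 bp. All comparisons
are **strict**, following the "<"/">" wording of the underlying QC
conventions: a sample with exactly 30 calls, waviness exactly 0.03 and
call rate exactly 0.96 survives, as does a call with 10 probes over
exactly 200,000 bp. Coordinates are 1-based inclusive (PennCNV dialect),
so interval length is `end - start + 1` and overlap length is
`max(0, min(ends) - max(starts) + 1)`.

A call matches a multi-gene locus when its dosage state equals the locus
dosage, it covers **strictly more than half** of the critical interval
(the overlap fraction is computed against the critical interval, not the
call), and it fully contains every key gene. Single-gene loci use
dosage-specific rules: deletions match when they intersect at least one
exon by one base pair or more; duplications only when they contain the
entire gene span.

Classification is a partition: `excluded_qc` (sample QC failed, checked
first), `carrier` (≥1 surviving call matches a schizophrenia-associated
locus), `excluded_pathogenic` (no SCZ match but a match to another
pathogenic neurodevelopmental locus), else `non_carrier`. A participant
matching both an SCZ locus and another pathogenic locus is a genuinely
open design point — the contrast is defined against participants without
*any* pathogenic CNV, which leaves dual carriage unspecified. We classify
such participants as carriers (SCZ takes precedence) and flag them in a
`dual_carrier` column so a sensitivity analysis can drop them.

The bundled locus file (`extdata/scz_loci_synthetic.json`) is a
**synthetic** stand-in: approximate GRCh37 coordinates for eight
SCZ-associated loci (including the single-gene NRXN1 locus with invented
exon structure) and five other pathogenic loci. It exists so the matching
rules can be exercised; it is not a curated clinical resource.

## Phenotype preparation

Participants are excluded by self-reported diagnosis codes and by ICD-10
codes. ICD-10 entries may be plain codes, matched as prefixes after dot
removal (`F25` catches `F25.1`), or category ranges such as `F11-F19`,
matched on the letter and two-digit category of the participant's code.

Extreme regional values are set missing when they lie strictly beyond
2.5 SD of the region's mean. The mean and SD are computed **once** over
all non-missing values of the region in the pooled analysis sample
(carriers + non-carriers), not iterated and not per group: "the group
mean" is ambiguous between those readings, and the pooled single-pass
version is the one whose behaviour is order-independent. Because
re-applying the rule would re-fence on post-removal moments and remove
more, the cohort object records a per-assay flag and `removeOutliers()`
refuses to run twice. The fence is strict — a value at exactly
mean ± 2.5 SD is kept — because the fence value itself is the boundary of
"non-extreme".

Whole-brain summaries tolerate the scattered missingness that outlier
removal creates: mean thickness is the mean over available regions, and
total surface area is the mean over available regions rescaled by the
region count (at the realized missingness rate of ~1% per region this is
indistinguishable from the complete-data sum while keeping every
participant in the analysis).

## Association model

Each outcome (a region, or a whole-brain summary) is regressed on a
carrier indicator plus covariates (default: age, sex, intracranial
volume, assessment centre) by OLS, complete-case per outcome. Two-sided
p-values come from the t distribution. By default the outcome and
continuous covariates are z-scored so betas are in outcome-SD units and
comparable across regions and measures; `standardize = FALSE` restores
raw-scale coefficients. Dropping `icv` from `covariates` reproduces the
head-size-unadjusted sensitivity analysis; ancestry principal components
can be appended the same way. Collinear covariates and zero-variance
outcomes are hard errors, as is an empty contrast level.

FDR control is BH step-up at q = 0.10. Families are declared, not
inferred: the whole-brain battery forms one family whose declared size
must equal the number of p-values in it (a mismatch is a hard error, so a
family can never silently drift), and each contrast's regional battery
forms a 68 regions × 2 measures = 136-test family. The whole-brain
family size is configurable because the same battery can be counted with
or without the any-carrier rows (14 = 7 contrasts × 2 measures when the
any-carrier contrast is included alongside six per-locus contrasts;
12 when only the per-locus rows are counted). Per-locus contrasts are
only fitted for loci carried by more than two participants.

## Structural covariance

For each pair of gyri, the Pearson correlation of the regional measure
across the participants of one group is Fisher z-transformed:
`z = atanh(r)`. Correlations are clamped to ±(1 − 1e-12) first so a
degenerate perfect correlation stays finite (z ≈ 13.9) instead of
becoming infinite. Cells with fewer than three pairwise-complete
observations, or involving a constant region, are missing (with a
warning). A gyrus's **integration index** is the mean of its z values
with the 67 other gyri; the **overall covariance** is the unweighted mean
of the 68 integration indices.

Correlations are computed on raw measures by default — the covariance
analysis is deliberately unadjusted — with `residualize = TRUE` available
to regress the association covariates out of every region first as a
sensitivity analysis.

**ICA weighting.** One independent component analysis per measure is fit
on the pooled (carriers + non-carriers) standardized participants × gyri
matrix, k = 20 components, so both groups are evaluated on identical
components. The mixing matrix is converted to non-negative relative
weights, `w_cg = |a_cg| / Σ_g |a_cg|`, which resolves ICA's sign and
scale indeterminacy; component order (itself arbitrary) is fixed by
sorting on total absolute mixing mass. A component's covariance is then
the weighted mean `Σ_g w_cg · idx_g` of the integration indices — the
weights sum to one, so no further division by the gyrus count is applied.
The FastICA fixed-point algorithm (logcosh contrast, symmetric
decorrelation) is implemented in the package and verified by a
blind-source-recovery test on data generated from disjoint non-Gaussian
sources.

One behaviour deserves emphasis: on data with little excess kurtosis —
including this package's own Gaussian generator — the logcosh contrast
surface is flat (by Stein's identity the fixed-point update direction for
a Gaussian projection is pure noise), so the iteration legitimately hits
its cap without meeting the tolerance. The fitted rotation is still an
orthonormal basis of the whitened space and is deterministic given the
seed, so its absolute-weight summaries remain usable for the weighting
role. `fitComponents()` therefore warns rather than errors by default;
`onNoConvergence = "error"` restores the strict behaviour with iteration
diagnostics.

**Resampling null and empirical p.** A group of non-carriers the same
size as the carrier group is drawn by simple random sampling without
replacement; the statistic (pairwise cell, integration index, component
value, or overall) is evaluated on it by exactly the same code path as
for the carriers — same clamping, same missing-data rules. Replicates
are drawn independently (overlap between replicates is allowed). The
empirical p-value is the fraction of replicates whose statistic exceeds
the observed one in absolute value (strict exceedance); a smoothed
variant `(count + 1)/(B + 1)`, which never returns exactly zero, is
available by flag. The reference replicate count is B = 100,000, which
resolves p-values to 1e-5 and reproduces the reporting granularity of a
full-scale run ("p < 0.0005" = fewer than 50 exceedances); tests and the
desk-scale acceptance run use B = 1,000–2,000, chosen so the whole
analysis completes in minutes on one CPU while still resolving p to
5e-4–1e-3. Per-gyrus and per-component empirical p-values are BH-flagged
at q = 0.10.

## The synthetic-cohort generator

On a standardized scale, the value of region *g* for participant *i* is

    z_ig = δ·carrier_i + X_i β + b_grp(i)·f_i + ε_ig

with one latent factor f per measure, ε ~ N(0, noiseSd²), and the values
affinely mapped to measurement units (thickness: region means 2.0–3.0 mm,
scale 0.12 mm; area: region means 1,000–4,000 mm², scale 330 mm²). The
single shared factor is the minimal generator of exchangeable positive
inter-regional covariance: any two regions of a participant in group
*grp* correlate at r = b²/(b² + noiseSd²) (`loadingForCorrelation()`
inverts this), and group differences enter only through the mean shift δ
and the loading b. This is all the analysis consumes — first and second
moments — which is why a richer generative model was not used.

Defaults mirror the study conditions the pipeline is designed for:
16,670 non-carriers; 120 carriers split as 15q11.2del = 59 (49%),
16p13.11dup = 18, 1q21.1dup = 14, 1q21.1del = 11, 16p11.2dup = 10,
2p16.3del = 8 (the per-locus split beyond "49% 15q11.2 deletion, six loci
with >2 carriers, 59 vs 61" is the package's own choice); 320
diagnosis-code exclusions, 980 sample-QC failures and 444 other
pathogenic carriers, so the participant funnel is 18,534 → 18,214 →
17,234 → 16,790. Covariates are drawn as age ~ U(45, 80) years,
sex ~ Bernoulli(0.53) (1 = female), ICV ~ N(1.55×10⁶, 1.5×10⁵) mm³,
centre ~ Bernoulli(0.157) (the two-centre imbalance), all with linear
effects. Default mean shifts are −0.020 SD (surface area) and +0.015 SD
(thickness) for every locus; default loadings imply inter-regional
correlations tanh(0.31) vs tanh(0.22) for thickness and tanh(0.16) vs
tanh(0.14) for surface area (carriers vs non-carriers). Outliers are
injected by replacing a value with its region mean ± 6 region SDs, which
the 2.5-SD fence provably removes.

When covariate effects are non-zero their shared signal adds a small
common-variance term on top of b², so the realized inter-regional
correlation slightly exceeds the factor-implied value; calibration
simulations that target an exact r therefore set the covariate effects
to zero.

The CNV fixture generator emits, with ground-truth labels: one
locus-matching call per configured carrier (single-gene deletion carriers
get a call clipping only the first exon, exercising the exon rule), one
pathogenic-locus call per pathogenic carrier, configurable numbers of
calls failing the probe-count and density filters, sample-QC failures
cycling through the three rules, and benign background calls placed on
chromosomes carrying no locus so they can never match.

**What the generator does not emulate:** spatial covariance structure
beyond one factor (no lobe-level blocks, no hemispheric symmetry), site
or scanner batch effects beyond a mean shift, non-Gaussian morphometry
distributions, genotype-derived ancestry structure, and any relationship
between a carrier's locus and *which* regions shift. Passing tests
demonstrate the statistical machinery is correct under the stated model;
they do not certify effect sizes or component structure on real cohort
data — in particular, ICA components on Gaussian simulations are
unidentifiable (see above) and only the weighting mechanics are
validated there.

## Numerical and reproducibility choices

- All seeded operations run under a private RNG stream and restore the
  caller's `.Random.seed`.
- For complete data the z-matrix uses a single BLAS crossprod; with
  missing values it falls back to pairwise-complete correlations. The two
  paths agree to ~1e-15 and each is bitwise-deterministic.
- r is clamped at ±(1 − 1e-12) before `atanh`; the probe-density filter
  compares `n_probes × 20000 < length` in exact integer-valued double
  arithmetic, so the boundary density of exactly 1/20,000 survives.
- ICA inputs are column-standardized; missing values are mean-imputed
  per region for the component fit only (the covariance statistics keep
  their own missing-data rules).
- The pipeline records per-stage input/kept/excluded counts (which must
  conserve) and an md5 hash of the canonical JSON of its full
  configuration, so any option change is visible in provenance.

## Problem sizes used in the shipped checks

The package's own test suite validates: filter and matching rules against
labelled fixtures (~200 samples, ~1,000 calls); BH against a naive
step-up oracle on 1,000 random p-vectors; covariance statistics against
double-loop oracles and exhaustive subset enumeration (7 choose 3);
type-I error of the overall empirical p (200 simulated studies of
120 vs 2,000 participants, B = 1,000; rejection rate and a KS uniformity
check); power for the r = 0.30 vs 0.22 covariance contrast (100 studies,
same sizes, ≥90% rejection, realized mean z within ±0.03 of atanh
targets); regression recovery of δ = −0.3 at n = 2,000 over 500
replicates; and bitwise reproducibility of the full pipeline. The
acceptance script runs the default 18,534-participant cohort with
B = 2,000. These sizes are the package's chosen desk-scale study
conditions.

## Known limitations

- The generator's Gaussianity makes ICA components unidentifiable there;
  blind-source recovery is validated on separate non-Gaussian synthetic
  sources.
- The 2.5-SD fence's "group mean" is implemented as the pooled analysis
  sample; per-group fencing would remove slightly different values.
- Dual SCZ + other-pathogenic carriage is resolved by SCZ precedence and
  a flag; either convention is defensible.
- Null replicates are independent draws; enumeration without replacement
  across replicates is available only via the exhaustive mode.
- Empirical p-values from size-matched resampling are exactly calibrated
  only when the non-carrier pool is large relative to the carrier group.
  All null subsets share one finite pool, so conditional on the pool the
  null distribution is slightly under-dispersed relative to an
  independent carrier draw, inflating the type-I rate by a factor that
  shrinks roughly like sqrt((1/m − 1/N)/(1/m + 1/N)) as the pool size N
  grows against the carrier count m. The package's type-I simulation
  (120 carriers vs a 2,000-participant pool) measures this inflation
  directly; at the default 16,670-participant pool the effect is
  negligible.
- Manual curation steps of real CNV workflows (visual inspection of
  calls) are out of scope.
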