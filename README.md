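# temponet

Temporal clustering coefficients of dynamic functional brain networks,
with test–retest reliability (ICC(3,1)) and sex/age group statistics —
plus a synthetic cohort generator with a known ground truth so the whole
pipeline can be validated at desk scale.

## Who it is for

Researchers working with region-of-interest (ROI) fMRI time series who
want a reproducible, fully tested implementation of the
sliding-window → binary multilayer network → temporal clustering
pipeline, and methodologists who want to study the statistical behaviour
of that pipeline (reliability, power, type-I error) on simulated cohorts
where the truth is known.

## The statistic

A run of T timepoints is tiled into overlapping windows (reference
configuration: width 139 TRs = 100.08 s, step 8 TRs = 5.76 s at
TR = 0.72 s, giving 133 windows per 1200-timepoint run). Each window's
Pearson correlation matrix is binarized by proportional thresholding at
densities 1–50% (keep the round(d·N(N−1)/2) strongest connections). On
the resulting binary layers a_ij(t), the nodal temporal clustering
coefficient is

    C_i = 1/(T−1) · Σ_t  [ Σ_j a_ij(t) a_ij(t+1) ] /
                         sqrt( Σ_j a_ij(t) · Σ_j a_ij(t+1) )

— the average overlap of node i's neighbour sets in consecutive windows,
normalized by the geometric mean of the two degrees, so C_i ∈ [0, 1].
Global and subnetwork values are unweighted means of nodal values.
Reliability across repeated runs is ICC(3,1) = (BMS − EMS)/(BMS +
(k−1)·EMS) per density, averaged over the density grid ("overall ICC")
and classified poor/moderate/good/excellent at 0.4/0.6/0.75. Sex effects
use the between-subject stratum of a repeated-measures ANCOVA (density
within-subject), age effects a partial Spearman correlation adjusted for
sex, education and head motion, both Bonferroni-corrected.

Design conventions (signed-correlation ranking, tie-breaking, rounding,
the isolated-node convention, covariate handling) are documented in the
methods vignette, `vignettes/temporal-clustering.Rmd`.

## Worked example

Simulate a test–retest cohort with a planted female persistence effect,
compute the metric table, and run the reliability and group analyses:

```r
library(temponet)

spec <- synthSpec(nSubjects = 40, kRuns = 4, tPoints = 300, seed = 42)
sim  <- simulateCohort(spec, intendedWindowWidth = 20)
sim$cohort
#> Cohort: 40 subjects (25 male, 15 female), 4 run(s) each
#>   age 22.0-36.7 y, mean FD 0.091-0.337 mm

ws  <- windowSpec(20, 20)   # non-overlapping 20-TR windows
tab <- computeCohortMetrics(sim$cohort, sim$parcellation, ws,
                            densities = seq(0.1, 0.5, by = 0.1),
                            metrics = "temporal_clustering")
head(tab, 3)
#>   subject  run density                   scope              metric     value
#> 1  sub001 run1     0.1                  global temporal_clustering 0.2696854
#> 2  sub001 run1     0.1 subnetwork:default-mode temporal_clustering 0.2320801
#> 3  sub001 run1     0.1     subnetwork:salience temporal_clustering 0.3271304

iccTable(tab, sim$cohort, scopes = "global")[[1]]
#> IccResult [temporal_clustering, global]: overall ICC 0.415 +/- 0.198 (moderate), 5 densities

avg <- averageRuns(tab)
sexContrast(avg, sim$cohort, nTests = 2)
#>    scope              metric        F pUncorrected   pCorrected direction nTests
#> 1 global temporal_clustering 28.92305 5.104463e-06 1.020893e-05         1      2

ageCorrelation(avg, sim$cohort, nTests = 2)
#>    scope              metric      rho pUncorrected pCorrected nTests
#> 1 global temporal_clustering 0.132518    0.4342932  0.8685863      2
```

Reading the output: across the four runs the density-averaged global
temporal clustering coefficient is moderately reliable (overall ICC
0.415, SD 0.198 over densities). The planted +20-timepoint female dwell
shift is detected (F = 28.9, corrected p ≈ 1e-05, direction +1 =
female > male), while the small planted age slope yields only a weak,
non-significant positive partial rho at this sample size — exactly the
qualitative pattern such a cohort should show.

Real data enter through `readTimeSeries()` (delimited T×N matrices),
`readParcellation()` (node → subnetwork TSV) and `readCohort()` (CSV
manifest with covariates and run paths); results leave through
`writeMetricTable()` and `iccSummaryTable()`.

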