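---
title: "Temporal clustering of dynamic brain networks: methods and design"
author: "temponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal clustering of dynamic brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temponet)
```

## What the package computes

Resting-state functional connectivity is not static: the correlation
structure between brain regions reorganizes on the scale of tens of
seconds. A standard way to quantify how *persistent* that structure is
is to segment each scan into sliding windows, estimate a connectivity
matrix per window, binarize each matrix, and ask how consistently each
node keeps its neighbours from one window to the next. temponet
implements that pipeline end to end, together with the two analyses
usually layered on top of it: test–retest reliability across repeated
runs (ICC(3,1)) and group statistics for sex and age effects.

The package is aimed at desk-scale methodological work: every analysis
step is exercised against a bundled synthetic cohort generator with a
known ground truth, so recovery of planted effects can be verified
without access to any large neuroimaging repository.

## The dynamic pipeline

**Sliding windows.** A run of $T$ timepoints is tiled with windows of
width $w$ TRs moved by a step of $s$ TRs. Windows are half-open
intervals $[t, t+w)$ starting at $0, s, 2s, \dots$; trailing timepoints
that do not fill a complete window are discarded, giving
$\lfloor (T-w)/s \rfloor + 1$ windows. The reference configuration
(width 139 TRs, step 8 TRs, TR = 0.72 s) tiles a 1200-timepoint run
into 133 windows of 100.08 s moved by 5.76 s.

**Window correlations.** Within each window the $N \times N$ Pearson
correlation matrix of the node signals is computed. A node with zero
variance inside a window is an error naming the window and node; the
synthetic generator avoids this by construction (every node carries
Gaussian noise).

**Proportional thresholding.** At density $d$ the
$k = \mathrm{round}(d \cdot N(N-1)/2)$ strongest connections are kept
and set to 1. Three conventions are fixed so results are
bit-reproducible:

* *Ranking* is by signed correlation by default. On data denoised
  without global-signal regression the strongest edges are
  overwhelmingly positive, and signed ranking is the common toolbox
  behaviour; ranking by magnitude is available via
  `rankBy = "absolute"`. At high densities the signed default can admit
  negative correlations into the retained set; this is deliberate and
  exposed rather than silently excluded.
* *Rounding* of $d \cdot N(N-1)/2$ is half-away-from-zero
  (`floor(x + 0.5)`), documented because floor vs round changes edge
  counts at exact halves.
* *Ties* at the cutoff are broken by ascending $(i, j)$ lexicographic
  pair order after sorting by value descending — deterministic and
  platform-independent.

Thresholding every window at every density of the default sweep
(1–50% in 1% steps) yields 50 binary multilayer networks per run. Edge
sets are nested across densities by construction.

## Temporal clustering coefficient

For binary layers $a_{ij}(t)$, the nodal temporal clustering
coefficient of node $i$ is

$$C_i = \frac{1}{T-1} \sum_{t=1}^{T-1}
  \frac{\sum_j a_{ij}(t)\, a_{ij}(t+1)}
       {\sqrt{\sum_j a_{ij}(t) \cdot \sum_j a_{ij}(t+1)}},$$

the average overlap of consecutive neighbour sets normalized by the
geometric mean of the two degrees. By Cauchy–Schwarz every term lies in
$[0,1]$, and $C_i = 1$ exactly when the neighbour set is constant and
nonempty. Two conventions matter:

* *Denominator.* The geometric-mean (square-root) normalization is
  used. Without the square root the coefficient can exceed 1,
  contradicting its advertised range; the square-root form is also the
  one implemented in the standard temporal-networks toolboxes from
  which the metric originates.
* *Isolated nodes.* If node $i$ has degree 0 in layer $t$ or $t+1$
  that transition contributes 0 to the sum while the $1/(T-1)$
  normalization is kept. This keeps $C_i$ defined at very low
  densities, where layers may be empty. It is a documented convention,
  not a mathematical necessity.

The global coefficient is the unweighted mean over nodes; each
subnetwork coefficient is the unweighted mean over its member nodes
(nine canonical subnetworks by default: default-mode, salience, visual,
subcortical, auditory, frontoparietal, cinguloopercular, sensorimotor,
attention).

Internally two equivalent code paths exist: an explicit path that
materializes the binary layer stacks, and a rank-position path used in
simulation loops that evaluates the whole density sweep from one
edge ranking per window. The test suite pins them to each other at
1e-12 and both to a literal triple-loop evaluation of the formula.

## Static comparators

For comparison the binary clustering coefficient
$C_i = 2t_i / (k_i(k_i-1))$ and local efficiency
$E_{loc}(i) = \frac{1}{k_i(k_i-1)} \sum_{j \ne h \in N(i)} 1/d_{jh}(G_i)$
are computed on the static network built from the whole run with the
same thresholding code path. Local efficiency uses the
neighbour-subgraph distance convention (distances measured inside the
subgraph induced by $i$'s neighbours, $i$ excluded); unreachable pairs
contribute 0 but stay in the normalizer, and $k_i < 2$ scores 0 on both
metrics. Shortest paths are delegated to igraph; the conventions are
asserted against a hand-rolled BFS oracle in the tests.

## Test–retest reliability

For a subjects-by-scans panel $y_{sj}$ ($n$ subjects, $k$ scans),

$$\mathrm{ICC}(3,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS},$$

with $BMS$ the between-subjects mean square and $EMS$ the residual mean
square of the two-way decomposition in which the scan main effect has
been removed (subjects random, scans fixed). Removing the scan effect
makes the statistic a *consistency* measure: adding a distinct constant
per scan column leaves it exactly unchanged, which is the property that
distinguishes ICC(3,1) from the one-way ICC(1,1) and is asserted
numerically in the tests. Negative estimates are reported as computed,
not truncated.

ICCs are computed per density and scope; the *overall* ICC is the
unweighted mean across the density grid, reported with its SD and
classified as poor (< 0.4), moderate ([0.4, 0.6)), good ([0.6, 0.75])
or excellent (> 0.75). As printed, the criterion leaves exactly 0.75
unassigned; it is mapped to *good* — the conservative choice for a
measure-zero boundary. A perfectly constant panel has no defined ICC
and is reported as NaN with class "undefined". An optional
F-distribution confidence interval (`icc31ConfInt`) is provided; the
interval construction is this package's choice of standard method, not
a claim about how any particular study computed its error bars.

## Sex and age statistics

**Sex contrast.** The design is a repeated-measures ANCOVA with density
as the within-subject factor and sex as the between-subject factor,
covarying for age, education years and mean framewise displacement. In
a balanced design the between-subject stratum of that model is carried
entirely by each subject's mean over the density levels, so the
implementation computes the sex F exactly from the linear model
`densityMean ~ sex + age + education + meanFd`. This reproduces the
between-subject F without modelling the density main effect or
sphericity corrections, which the between-subject test does not need.
Covariates with zero variance are dropped (the model then degrades
gracefully to a one-way ANOVA); collinear covariates are a named
error. The reported direction is the sign of the adjusted
female − male coefficient.

**Age association.** The metric is averaged over the density grid per
subject and correlated with age by a partial Spearman correlation
adjusted for sex, education and motion: all variables are
rank-transformed (mid-ranks for ties), outcome and predictor ranks are
residualized on the covariate ranks by least squares, and the residuals
are correlated. With no informative covariates this reduces exactly to
the plain Spearman rho. The p value uses the t approximation with
$n - 2 - q$ degrees of freedom. Rank-basedness buys invariance to any
strictly monotone transform of every variable, asserted in the tests.

**Multiplicity.** Bonferroni correction within declared families:
2 tests at the global level and $2 \times 9 = 18$ at the subnetwork
level by default, with family sizes configurable per design. Sex and
age are tested in separate models. A sex-by-age interaction screen
(`interactionScreen`) adds the product term to the between-subjects
model and warns — without aborting — when its corrected p falls below
0.05.

## The synthetic cohort generator

The generator emulates the statistical structure the analyses assume:
between-subject variance, within-subject (between-run) error, and
additive sex/age effects, all acting on a single interpretable ground
truth — the mean *regime dwell time* $\lambda$ (timepoints). Per run,

$$\lambda = \text{baseDwell} + \text{sexEffect} \cdot 1[\text{female}]
 + \text{ageSlope} \cdot (\text{age} - \overline{\text{age}})
 + b_{\text{subject}} + e_{\text{run}},$$

with $b_{\text{subject}} \sim N(0, \sigma_{\text{subject}}^2)$ shared
across a subject's runs, $e_{\text{run}} \sim N(0, \sigma_{\text{run}}^2)$,
and $\lambda$ clipped at 2 to avoid degenerate single-sample regimes.
The time series is regime-switching Gaussian: regime durations are
geometric with mean $\lambda$ (memoryless, one parameter, easy oracle),
and each regime reassigns the nine subnetworks to a small number of
latent communities whose members share a common signal
(within-community correlation `regimeRho`). Longer dwell means
consecutive windows more often sample the same covariance regime, so
thresholded edges persist and the temporal clustering coefficient
rises — the mapping the monotonicity and power tests rely on.
Persistence is induced through dwell rather than through autocorrelated
edge weights because dwell maps directly onto the notion of connections
persisting across consecutive windows and gives a per-subject scalar
ground truth to correlate against.

Covariates are drawn as in a young-adult resting-state cohort: sex
Bernoulli(0.5), age uniform on 22–37 years, education $N(14, 2^2)$
years, mean framewise displacement log-normal around 0.15 mm.

**Calibration.** The default operating point was chosen once, where
the dwell-to-metric response is steep rather than saturated:
non-overlapping 20-TR windows on 300-timepoint, 20-node runs, with
baseDwell 25 and a female dwell shift of +20 timepoints against
$\sigma_{\text{subject}} = 12$ and $\sigma_{\text{run}} = 5$. At these
settings a cohort of 80 subjects with 2 runs detects the sex effect
with high power while the same test under a null effect rejects at its
nominal 5% rate, and across 60 subjects the planted dwell and the
measured global temporal clustering are strongly rank-correlated.
These sizes — 20 nodes, 300 timepoints, 80 subjects, 50 (power) and
200 (null) replicate seeds — are the package's validation problem
sizes; they are deliberately small enough to run on a laptop while
keeping the relevant test statistics well away from their decision
boundaries.

**What the generator does not emulate.** Hemodynamics, realistic fMRI
noise spectra (1/f, physiological cycles), spatial autocorrelation
within subnetworks beyond the shared community factor, motion
artifacts (mean FD is drawn independently of the signal), and
session-level drifts. Passing tests therefore demonstrate that the
estimators and tests recover the effects they target under the model's
assumptions — not that any particular reliability value will be
observed on real data.

## Numerical choices and degenerate inputs

* Oracle equivalence tolerances are 1e-12 (vectorized vs literal
  implementations); closed-form recovery tolerances are ±0.05 at
  n = 500 panels, matching the sampling error of the estimator.
* Zero-variance columns are rejected at construction, before any
  correlation is attempted, naming the column.
* Density sweeps that retain zero edges (possible for small N at 1%)
  warn and return empty layers; the temporal coefficient stays defined
  through the isolated-node convention.
* Metric tables are written at full double precision
  (17 significant digits) so writer/reader pairs are exact identities.
* All simulation entry points take an integer seed and restore the
  caller's RNG state (`withSeed`), making every pipeline product
  byte-reproducible.

## Known limitations

* Only the binary, undirected formulation is implemented; weighted
  multilayer extensions of the temporal clustering coefficient are out
  of scope.
* Tapered, DCC or phase-based dynamic connectivity estimators are not
  provided; windows are rectangular.
* The sex contrast models a two-level category; the repeated-measures
  model's within-subject stratum (density main effect, density-by-sex
  interaction) is not tested, as only the between-subject effect is of
  interest here.
* ICC confidence intervals use the standard F interval; other
  constructions (bootstrap, variance-component intervals) are not
  offered.
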