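---
title: "Methods: individualized network models of tau spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized network models of tau spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic cohort does and does
not establish.

## 1. The pathology index

Flortaucipir-class tau tracers show off-target binding in basal ganglia,
thalamus and choroid plexus, so raw SUVR mixes pathologic and non-specific
signal. The package therefore works on a tau pathology index. Per region,
SUVR pooled across subjects is fit by maximum likelihood with one- and
two-component Gaussian mixtures:

* the one-component fit is the closed-form Gaussian MLE;
* the two-component fit is EM initialized from a median split, with 5
  additional restarts from perturbed means, keeping the best log-likelihood.

**Model selection.** A region is retained when the two-component model has
the lower BIC (the two extra parameters of the second component are
penalized by `3 log n`). "Better fit" is not otherwise pinned down by the
problem, and BIC is the standard consistent criterion for mixture order
selection; AIC is available by flag for users who prefer a more liberal
rule. Two degenerate situations are resolved conservatively: coincident
component means count as unimodal, and a fit whose every EM start collapsed
onto the variance floor is a spike, not a pathologic distribution, and also
counts as unimodal (without this guard a floored spike component can have
arbitrarily large likelihood and falsely "retain" a pure-noise region).

**The index.** For a retained region with non-pathologic (lower-mean) and
pathologic (higher-mean) component CDFs `F_n`, `F_p`,

```
TPI(x) = F_p(x) + F_n(x) - 1 .
```

"Percentile on a component" is read as the component's own Gaussian CDF —
the relative position of the SUVR value on each curve — rather than the
posterior membership probability; only the CDF reading produces an index
that is strictly increasing in SUVR and spans (−1, 1), with −1 far below
both components and +1 far above both.

**Numerics.** EM tolerance is `1e-8` on the log-likelihood; the variance
floor is `1e-6` of the sample variance; at least 20 observations are
required per region; component labels are assigned by mean order at
transform time, so storage order is irrelevant. Constant input returns the
floored one-component fit deterministically.

## 2. Epicenters

TPI is z-scored within each subject across retained regions (sample SD,
`n − 1`); regions at or above the threshold are epicenters. The default
threshold 1.645 is the 95th percentile of the standard normal; 1.96 and
2.32 are supported as stricter sensitivity settings, and raising the
threshold can only shrink a subject's set (tested as an invariant). The
inclusive `≥` is used; for continuous data the distinction is immaterial. A
zero-variance subject yields an empty set plus a warning, and subjects with
zero epicenters are excluded from every statistical stage (they still
contribute to the group connectome if they are CU amyloid-negative). The
canonical group epicenter is the bilateral entorhinal cortex, the
stereotypical earliest cortical Braak region.

Epicenter frequency agreement between folds is summarized with ICC(2,1) —
two-way random effects, absolute agreement, single measures. The ICC form
was an open choice; ICC(2,1) is the conservative convention when raters
(folds) are exchangeable random draws and absolute agreement matters.

## 3. Connectome distances

Raw tractography matrices are seed-normalized streamline proportions and
mildly asymmetric, so matrices are symmetrized by the arithmetic mean of the
two directed entries (order-independent), the diagonal zeroed, and the
weakest 10% of strictly positive undirected edges removed globally
(count floored, ties broken by row-major position for determinism). Edge
cost is the reciprocal weight; zero-weight pairs are non-edges rather than
infinite-cost edges; Dijkstra's algorithm (via `igraph`) yields all-pairs
distances, with unreachable pairs reported as `Inf` rather than raised.
The graph keeps **all** parcellation nodes — regions excluded from PET
analysis may still lie on shortest paths — while distance profiles are
reported only for retained regions.

The group connectome averages the raw matrices of CU amyloid-negative
subjects before thresholding, and is computed once on all such subjects
(recomputing per training fold is exposed by the `select` argument; the
fold-wise reading of the procedure changes the group matrix by a few
subjects out of a hundred and was not made the default).

The average-distance profile of a subject under a variant is the mean
shortest-path distance of each retained region from the epicenter set; a
region that is itself an epicenter contributes its zero self-distance.
Infinite entries are dropped from the mean with a logged count.

## 4. Group models, validation, and comparisons

Within each training split, every subject's regions are sorted by raw TPI
descending (ties by region label) and the same permutation is applied to
the covariate-adjusted TPI and to all four distance profiles; averaging at
each rank then gives group vectors that are comparable across subjects with
different epicenters. Ranking uses **raw** TPI while averaging uses
**adjusted** TPI: the adjustment removes between-subject nuisance shifts,
and because the residualization applies a single subject-level offset per
region set, it cannot reorder regions within a subject — so ranking on raw
values is both faithful to "ordering by tau burden" and identical to
ranking on conditional residuals.

Covariate adjustment is a linear mixed model over all region-level
observations — fixed effects of age, sex, education, race, PET–dMRI
interval, and study, random intercept per participant — with conditional
residuals as the adjusted values; a fixed-effects OLS fallback exists for
singular fits and as a faster option.

Each variant is fit by OLS of mean adjusted TPI on mean distance (64 points,
residual df 62), with standardized β computed on z-scored variables. The
five folds are stratified on amyloid status (per-fold stratum counts within
one subject). Held-out evaluation applies the training coefficients to the
test distances and regresses measured on predicted TPI, so a working model
has positive β; regressing measured on predicted (not the reverse) was
chosen because it makes the test-set β a bounded correlation-scale quantity.
Per-fold R² vectors are compared by paired t-tests (df 4), with an infinite-t
guard for constant differences. The amyloid interaction stacks the
amyloid-positive and amyloid-negative rank-averaged vectors (2 × 64 points)
and tests the Distance × status term.

Subject-level effect sizes apply the fold-averaged amyloid-positive training
coefficients to each subject's own profile; summary statistics per variant
are reported as the mean of per-fold/per-subject standardized fits rather
than one pooled fit. The four variants are compared with a one-way
repeated-measures ANOVA (`F = MS_condition / MS_error`,
df `(k−1, (k−1)(n−1))`) without sphericity correction — with four conditions
and the magnitudes involved the correction does not change conclusions, and
uncorrected df match the conventional reporting style — followed by paired
t-tests Bonferroni-scaled by the six pairs actually tested.

## 5. Longitudinal models

Annualized change is `(follow-up − baseline) / interval` on the TPI scale.
Subjects are rank-aligned by **baseline** TPI (aligning by change rank is
available via `rank_on = "change"` but not default: baseline rank keeps the
distance profiles aligned to the same permutation used cross-sectionally). Each
variant's model is a two-predictor OLS of rank-averaged annualized change on
distance and baseline TPI over the full longitudinal subset (no splitting:
the subset is small), reporting the distance term's standardized β with 95%
CI.

Variants are compared with Hittner's modification of the Dunn–Clark Z for
two dependent overlapping correlations: Fisher z-difference divided by its
standard error, with the covariance term evaluated at the backtransformed
mean of the two Fisher z's. The correlation underlying each variant is taken
between its distance vector and the outcome residualized on baseline TPI
(the covariate-adjusted association the two-predictor fit estimates); a
semipartial option additionally residualizes the distance vectors and is
reported alongside. The test's type-I error at `n = 64` is verified by
Monte-Carlo calibration in the test suite, and identical predictors
short-circuit to `Z = 0` exactly.

## 6. The synthetic cohort

No public data with the required structure (per-subject tractography plus
tau PET) exists, so the generator is a first-class, tested module whose
defaults define the study conditions.

* **Parcellation**: 104 regions in bilateral pairs; 40 designated
  non-specific (unimodal SUVR, `σ = 0.10`), 64 mixture regions with
  non-pathologic means near 1 (`σ_n = 0.08`) and pathologic components
  `+0.55` SUVR higher (`σ_p = 0.15`), about 4.8 pooled SDs of separation —
  "well-separated" as real off-target vs. tangle binding is.
* **Connectomes**: nodes embedded uniformly in a latent 3-D cube;
  log-weights `log(0.10) − d/0.75 + N(0, 1)`, exponentiated and clipped to
  \[0, 1\] — dense (>99% of pairs connected) and heavy-tailed, like
  normalized probabilistic-tractography matrices. Subject matrices multiply
  the template edge-wise by `exp(N(0, 0.6))` noise, a deliberately
  individual level of variation so that individual- and group-connectome
  variants are genuinely different models.
* **Epicenters**: 1–7 per subject, uniform, sampled with 10× weight on an
  8-region limbic pool (ERC, amygdala, hippocampus, parahippocampal),
  reproducing medial-temporal predominance with heterogeneity.
* **Tau**: a subject draws region `r` from the pathologic component with
  probability `min(1, 0.03 + severity · plogis(5 − 1.2 · d̄_r))`, where
  `d̄_r` is the true mean distance from the subject's own epicenters on the
  subject's own (full) graph. The floor keeps every mixture region bimodal
  at the cohort level; severity is `U(0.25, 0.65)` for amyloid-positive and
  `U(0.05, 0.25)` for amyloid-negative subjects (nonzero, so
  individual-epicenter models remain meaningful in the negative group). A
  subject's own epicenter regions draw from the upper (0.97, 0.998)
  quantiles of the *same* pathologic component — this makes them
  within-subject outliers without distorting the pooled per-region mixture
  (an additive mean shift was tried first and rejected: it corrupted the
  pooled pathologic component of the limbic regions and, through the
  mismatch between fitted and generative transforms, inverted the
  longitudinal partial distance effect). A small continuous mean shift
  `0.06 · severity · plogis(5 − 1.2 · d̄_r)` SUVR models sub-threshold tau,
  keeping the within-subject TPI ranking informative below the occupancy
  threshold as it is in real data.
* **Covariates**: standardized effects ≤ 0.1 (age, sex, education, race,
  study, scan interval), so residualization is exercised but never
  dominant.
* **Longitudinal**: a 0.6 fraction of amyloid-positive subjects gets a
  follow-up after `N(3.18, 1.35²)` years (resampled positive). Annualized
  change is imposed on the TPI scale, `0.018 − 0.002 · d̄_r` per year plus
  `N(0, 0.003)` noise, clipped inside (−1, 1) and mapped back to SUVR
  through the inverse of the region's generative transform. Imposing the
  drift on the TPI scale (rather than SUVR) is what makes the generative
  slope exactly recoverable by regression — an SUVR-scale drift is
  modulated by the strongly varying slope of the TPI transform and has no
  single recoverable coefficient.

**What passing tests show — and don't.** The generator reproduces the
*structure* the analysis assumes: bimodal regional SUVR over a cohort,
distance-graded occupancy from person-specific origins, dense heavy-tailed
connectomes, covariate nuisance, and proximity-graded accumulation. It does
not emulate spatial autocorrelation of neighboring regions, scanner/site
batch structure, longitudinal attrition, registration error, or partial
volume effects; recovery of the generative ordering here demonstrates that
the pipeline estimates what it claims to estimate when its assumptions
hold, not that those assumptions hold in any particular imaging cohort.

## 7. Problem sizes and runtime choices

The validation suite uses 100 cohorts of 200 subjects for the
cross-sectional ordering checks, 100 cohorts of 50 subjects (all-follow-up,
0.5 positivity) for longitudinal sign recovery, one 300-subject cohort for
the region-exclusion counts, 10⁴ replicates for the dependent-correlation
calibration, and 20 template connectomes for the threshold-stability check;
these sizes give stable Monte-Carlo estimates of each property on a single
CPU. Mixture fits inside the large loops use a single EM start: with
components ~5 SDs apart the median-split start converges to the global
optimum, and the restart machinery exists for less separated data.

## 8. Known limitations

* The rank-alignment step makes group vectors monotone by construction;
  R² of the group fits should be read as ordering-conditional variance
  explained, not voxel- or region-level accuracy.
* TPI compresses near ±1, so longitudinal change in nearly saturated
  regions is attenuated; the baseline covariate absorbs most but not all of
  this, which is the main reason the longitudinal distance β is estimated
  with wider intervals than the cross-sectional one.
* With a fixed within-subject z threshold the number of detected epicenters
  tracks the spread of a subject's TPI distribution; in high-burden
  subjects detection is systematically more liberal than the generative
  truth.
* Hittner's Z assumes jointly normal ranks-averaged vectors; with 64 ranks
  the normal approximation is good (verified by simulation) but the test is
  not exact.
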